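#' Dataset record
#'
#' A sequence together with its reference structure and family label.
#'
#' @param seq An [rna_sequence].
#' @param structure An [rna_structure] with `n` equal to the sequence
#'   length.
#' @param family Family label (e.g. "5sRNA", "tRNA"); labels come from the
#'   dataset manifest or directory layout, never from sequence content.
#' @return A list of class `dataset_record`.
#' @export
dataset_record <- function(seq, structure, family = "unknown") {
  stopifnot(inherits(seq, "rna_sequence"), inherits(structure, "rna_structure"))
  if (structure$n != seq$n) {
    stop("structure length ", structure$n, " does not match sequence length ",
         seq$n, " for '", seq$id, "'")
  }
  structure(list(seq = seq, structure = structure,
                 family = as.character(family)),
            class = "dataset_record")
}

#' Read sequences from a FASTA file
#'
#' @param path FASTA file. Lowercase and `T` are normalised (see
#'   [rna_sequence]).
#' @return List of [rna_sequence]; empty list (with a warning) for an
#'   empty file.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0L) {
    warning("empty FASTA file: ", path)
    return(list())
  }
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  mapply(function(s, id) rna_sequence(s, id = id),
         as.character(set), ids, SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Write sequences to a FASTA file
#'
#' @param seqs List of [rna_sequence].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  lines <- unlist(lapply(seqs, function(s) c(paste0(">", s$id), s$bases)))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write connectivity-table (CT) files
#'
#' Standard 6-column CT: a header line `<n> <id>` followed by one row per
#' base with columns index, base, previous, next, partner (0 = unpaired),
#' index. Partner symmetry is verified: if row `i` names partner `j`, row
#' `j` must name `i`.
#'
#' @param path CT file path.
#' @param family Family label attached to the record.
#' @return `read_ct`: a [dataset_record]. `write_ct`: `path`, invisibly.
#' @export
read_ct <- function(path, family = "unknown") {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("CT file too short: ", path)
  head_tok <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  n <- suppressWarnings(as.integer(head_tok[1]))
  if (is.na(n)) stop("CT header must start with the sequence length: ", path)
  id <- if (length(head_tok) > 1) head_tok[2] else basename(path)
  if (length(lines) < n + 1L) {
    stop("CT file ", path, " declares ", n, " bases but has only ",
         length(lines) - 1L, " rows")
  }
  rows <- strsplit(trimws(lines[2:(n + 1L)]), "\\s+")
  idx <- vapply(rows, function(r) as.integer(r[1]), integer(1))
  base <- vapply(rows, function(r) r[2], character(1))
  partner <- vapply(rows, function(r) as.integer(r[5]), integer(1))
  if (!identical(idx, seq_len(n))) stop("non-sequential CT indices in ", path)
  if (any(partner < 0L | partner > n)) stop("CT partner index out of range in ", path)
  for (i in seq_len(n)) {
    j <- partner[i]
    if (j != 0L && partner[j] != i) {
      stop("CT partner asymmetry in ", path, ": line ", i + 1L, " (base ", i,
           ") names partner ", j, " but line ", j + 1L, " (base ", j,
           ") names partner ", partner[j])
    }
  }
  sel <- which(partner > idx)
  dataset_record(rna_sequence(paste(base, collapse = ""), id = id),
                 rna_structure(cbind(idx[sel], partner[sel]), n = n),
                 family = family)
}

#' @rdname read_ct
#' @param record A [dataset_record].
#' @export
write_ct <- function(record, path) {
  stopifnot(inherits(record, "dataset_record"))
  n <- record$seq$n
  partner <- integer(n)
  p <- record$structure$pairs
  if (nrow(p) > 0) {
    partner[p[, 1]] <- p[, 2]
    partner[p[, 2]] <- p[, 1]
  }
  bases <- strsplit(record$seq$bases, "")[[1]]
  rows <- sprintf("%d %s %d %d %d %d", seq_len(n), bases,
                  seq_len(n) - 1L, c(seq_len(n - 1L) + 1L, 0L), partner,
                  seq_len(n))
  writeLines(c(sprintf("%d %s", n, record$seq$id), rows), path)
  invisible(path)
}

#' Read a BPSEQ file
#'
#' Standard 3-column BPSEQ (index, base, partner; 0 = unpaired); leading
#' `#` comment lines are skipped. Partner symmetry is verified as for CT.
#'
#' @param path BPSEQ file path.
#' @param family Family label.
#' @return A [dataset_record].
#' @export
read_bpseq <- function(path, family = "unknown") {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  if (length(lines) == 0L) stop("empty BPSEQ file: ", path)
  rows <- strsplit(trimws(lines), "\\s+")
  idx <- vapply(rows, function(r) as.integer(r[1]), integer(1))
  base <- vapply(rows, function(r) r[2], character(1))
  partner <- vapply(rows, function(r) as.integer(r[3]), integer(1))
  n <- length(idx)
  if (!identical(idx, seq_len(n))) stop("non-sequential BPSEQ indices in ", path)
  if (any(partner < 0L | partner > n)) {
    stop("BPSEQ partner index out of range in ", path)
  }
  for (i in seq_len(n)) {
    j <- partner[i]
    if (j != 0L && partner[j] != i) {
      stop("BPSEQ partner asymmetry in ", path, ": line for base ", i,
           " names ", j, " but base ", j, " names ", partner[j])
    }
  }
  sel <- which(partner > idx)
  dataset_record(rna_sequence(paste(base, collapse = ""),
                              id = sub("\\.bpseq$", "", basename(path))),
                 rna_structure(cbind(idx[sel], partner[sel]), n = n),
                 family = family)
}

#' Read / write dot-bracket files
#'
#' Records of the form `>id` / sequence line / structure line.
#'
#' @param path File path.
#' @param family Family label for all records.
#' @return `read_dotbracket_file`: list of [dataset_record]; empty list
#'   (with a warning) for an empty file.
#' @export
read_dotbracket_file <- function(path, family = "unknown") {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    warning("empty dot-bracket file: ", path)
    return(list())
  }
  starts <- grep("^>", lines)
  if (length(starts) == 0L || starts[1] != 1L) {
    stop("dot-bracket file must consist of '>id' / sequence / structure ",
         "records: ", path)
  }
  out <- vector("list", length(starts))
  for (r in seq_along(starts)) {
    s <- starts[r]
    if (s + 2L > length(lines) || (r < length(starts) && starts[r + 1L] != s + 3L)) {
      stop("truncated record '", lines[s], "' in ", path)
    }
    id <- sub("^>\\s*", "", lines[s])
    seq <- rna_sequence(trimws(lines[s + 1L]), id = id)
    st <- parse_dotbracket(trimws(lines[s + 2L]))
    if (st$n != seq$n) {
      stop("record '", id, "' in ", path, ": sequence length ", seq$n,
           " but structure length ", st$n)
    }
    out[[r]] <- dataset_record(seq, st, family = family)
  }
  out
}

#' @rdname read_dotbracket_file
#' @param records List of [dataset_record] (nested structures only).
#' @export
write_dotbracket_file <- function(records, path) {
  lines <- unlist(lapply(records, function(r) {
    c(paste0(">", r$seq$id), r$seq$bases, to_dotbracket(r$structure))
  }))
  writeLines(lines, path)
  invisible(path)
}

# Global-alignment percent identity of two records' sequences, in [0, 1].
seq_identity <- function(a, b) {
  al <- Biostrings::pairwiseAlignment(a$seq$bases, b$seq$bases,
                                      type = "global")
  Biostrings::pid(al) / 100
}

#' Remove duplicate and near-duplicate sequences
#'
#' Exact duplicate sequences are always removed (the first occurrence is
#' kept). With `identity_threshold < 1`, a record is additionally dropped
#' when its global-alignment identity to any already-kept record reaches
#' the threshold (greedy, deterministic in input order). The default 1.0
#' removes exact duplicates only: any looser notion of "similar" discards
#' data, so it is opt-in.
#'
#' @param records List of [dataset_record].
#' @param identity_threshold Value in `(0, 1]`.
#' @return Filtered list of records.
#' @export
remove_redundant <- function(records, identity_threshold = 1.0) {
  stopifnot(identity_threshold > 0, identity_threshold <= 1)
  if (length(records) == 0L) return(records)
  bases <- vapply(records, function(r) r$seq$bases, character(1))
  records <- records[!duplicated(bases)]
  if (identity_threshold >= 1) return(records)
  kept <- list(records[[1L]])
  for (r in records[-1L]) {
    sim <- vapply(kept, function(k) seq_identity(k, r), numeric(1))
    if (all(sim < identity_threshold)) kept[[length(kept) + 1L]] <- r
  }
  kept
}

#' Drop pseudoknotted structures
#'
#' Retains exactly the records whose structures contain no crossing pairs,
#' reporting per-family before/after counts. Pseudoknots are tertiary-
#' structure features outside the scope of nested decoding, so they are
#' removed before training or evaluation.
#'
#' @param records List of [dataset_record].
#' @param quiet Suppress the count report.
#' @return Filtered list of records.
#' @export
filter_pseudoknots <- function(records, quiet = FALSE) {
  if (length(records) == 0L) return(records)
  keep <- !vapply(records, function(r) r$structure$pseudoknotted, logical(1))
  if (!quiet) {
    fam <- vapply(records, function(r) r$family, character(1))
    before <- table(fam)
    after <- table(factor(fam[keep], levels = names(before)))
    for (f in names(before)) {
      message(sprintf("%s: %d before, %d after pseudoknot removal",
                      f, before[[f]], after[[f]]))
    }
  }
  records[keep]
}

#' Split a dataset into train / validation / test
#'
#' Disjoint, exhaustive partition in the given ratios (default 7:2:1),
#' deterministic given the seed. With `stratify_by_family`, the ratios are
#' honoured within every family (largest-remainder rounding).
#'
#' @param records List of [dataset_record].
#' @param ratios Three positive weights, default `c(7, 2, 1)`.
#' @param seed Integer seed.
#' @param stratify_by_family Stratify on the family label (default TRUE).
#' @return List with elements `train`, `validation`, `test`.
#' @export
split_dataset <- function(records, ratios = c(7, 2, 1), seed = 1L,
                          stratify_by_family = TRUE) {
  stopifnot(length(ratios) == 3L, all(ratios > 0))
  if (length(records) < 3L) {
    stop("need at least 3 records to form train/validation/test splits")
  }
  set.seed(as.integer(seed))
  alloc <- function(idx) {
    m <- length(idx)
    idx <- idx[sample.int(m)]
    exact <- m * ratios / sum(ratios)
    sizes <- floor(exact)
    rem <- m - sum(sizes)
    if (rem > 0) {
      extra <- order(exact - sizes, decreasing = TRUE)[seq_len(rem)]
      sizes[extra] <- sizes[extra] + 1L
    }
    split(idx, rep(1:3, times = sizes))
  }
  fam <- vapply(records, function(r) r$family, character(1))
  groups <- if (stratify_by_family) split(seq_along(records), fam)
            else list(seq_along(records))
  parts <- lapply(groups, alloc)
  take <- function(k) {
    ii <- sort(unlist(lapply(parts, function(p) p[[as.character(k)]]),
               use.names = FALSE))
    records[ii]
  }
  list(train = take(1), validation = take(2), test = take(3))
}

# Maximal stacked-run lengths of one structure: a stem is a run of pairs
# (i, j), (i+1, j-1), ...; a bulge breaks the run.
stem_lengths <- function(s) {
  p <- s$pairs
  if (nrow(p) == 0L) return(integer(0))
  p <- p[order(p[, 1]), , drop = FALSE]
  key <- paste(p[, 1], p[, 2])
  has_outer <- paste(p[, 1] - 1L, p[, 2] + 1L) %in% key
  lens <- integer(0)
  for (r in which(!has_outer)) {  # r starts a stem
    len <- 1L
    i <- p[r, 1]; j <- p[r, 2]
    while (paste(i + len, j - len) %in% key) len <- len + 1L
    lens <- c(lens, len)
  }
  lens
}

#' Dataset statistics for window sizing
#'
#' The window height is chosen as the dataset's maximum stem length (a stem
#' being a maximal run of stacked pairs; bulges break a stem) and the
#' target length as the mean sequence length rounded to the nearest
#' integer. This function computes both plus per-family length summaries.
#'
#' @param records List of [dataset_record].
#' @return List with `max_stem_length`, `mean_sequence_length` (rounded),
#'   and `family_lengths` (list of per-family sequence-length tables).
#' @export
dataset_stats <- function(records) {
  if (length(records) == 0L) {
    return(list(max_stem_length = 0L, mean_sequence_length = 0L,
                family_lengths = list()))
  }
  stems <- unlist(lapply(records, function(r) stem_lengths(r$structure)))
  lens <- vapply(records, function(r) r$seq$n, integer(1))
  fam <- vapply(records, function(r) r$family, character(1))
  list(max_stem_length = if (length(stems)) max(stems) else 0L,
       mean_sequence_length = as.integer(round(mean(lens))),
       family_lengths = lapply(split(lens, fam), table))
}
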