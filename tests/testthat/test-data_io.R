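make_records <- function(dbs, family = "fam") {
  lapply(seq_along(dbs), function(i) {
    st <- parse_dotbracket(dbs[[i]])
    s <- sequence_for_structure(st, gu_fraction = 0, seed = i,
                                id = sprintf("r%02d", i))
    dataset_record(s, st, family = family)
  })
}

test_that("FASTA reading normalizes case and T, and empty files warn", {
  f <- tmpfile(".fasta")
  writeLines(c(">s1 some description", "gattaca", ">s2", "GGGAAACCC"), f)
  seqs <- read_fasta(f)
  expect_equal(length(seqs), 2L)
  expect_equal(seqs[[1]]$id, "s1")
  expect_equal(seqs[[1]]$bases, "GAUUACA")
  empty <- tmpfile(".fasta")
  file.create(empty)
  expect_warning(out <- read_fasta(empty), "empty")
  expect_equal(out, list())
  # round trip
  f2 <- tmpfile(".fasta")
  write_fasta(seqs, f2)
  again <- read_fasta(f2)
  expect_equal(again[[2]]$bases, seqs[[2]]$bases)
})

test_that("CT files round-trip and partner asymmetry is reported with lines", {
  rec <- make_records("((...))")[[1]]
  path <- tmpfile(".ct")
  write_ct(rec, path)
  back <- read_ct(path, family = "fam")
  expect_equal(back$seq$bases, rec$seq$bases)
  expect_equal(back$structure$pairs, rec$structure$pairs, ignore_attr = TRUE)
  # a 5-base CT for "(...)" on GAAAC read directly
  ct <- c("5 tiny",
          "1 G 0 2 5 1", "2 A 1 3 0 2", "3 A 2 4 0 3", "4 A 3 5 0 4",
          "5 C 4 0 1 5")
  p2 <- tmpfile(".ct")
  writeLines(ct, p2)
  tiny <- read_ct(p2)
  expect_equal(tiny$structure$pairs, cbind(1L, 5L), ignore_attr = TRUE)
  # asymmetric partners name both offending lines
  bad <- ct
  bad[6] <- "5 C 4 0 2 5"  # 5 claims 2 but 2 claims 0
  p3 <- tmpfile(".ct")
  writeLines(bad, p3)
  err <- tryCatch(read_ct(p3), error = identity)
  expect_s3_class(err, "error")
  expect_match(conditionMessage(err), "asymmetry")
  expect_match(conditionMessage(err), "base 1")
  expect_match(conditionMessage(err), "base 5")
})

test_that("BPSEQ files parse with symmetry checks", {
  p <- tmpfile(".bpseq")
  writeLines(c("# comment", "1 G 6", "2 G 5", "3 A 0", "4 A 0",
               "5 C 2", "6 C 1"), p)
  rec <- read_bpseq(p)
  expect_equal(to_dotbracket(rec$structure), "((..))")
  bad <- tmpfile(".bpseq")
  writeLines(c("1 G 3", "2 A 0", "3 C 2"), bad)
  expect_error(read_bpseq(bad), "asymmetry")
})

test_that("dot-bracket files round-trip records and validate lengths", {
  recs <- make_records(c("((...))", ".....", "(((...)))"))
  path <- tmpfile(".db")
  write_dotbracket_file(recs, path)
  back <- read_dotbracket_file(path, family = "fam")
  expect_equal(length(back), 3L)
  for (i in 1:3) {
    expect_equal(back[[i]]$seq$bases, recs[[i]]$seq$bases)
    expect_equal(to_dotbracket(back[[i]]$structure),
                 to_dotbracket(recs[[i]]$structure))
  }
  mism <- tmpfile(".db")
  writeLines(c(">x", "GAAAC", "(....)"), mism)
  expect_error(read_dotbracket_file(mism), "length")
  empty <- tmpfile(".db")
  file.create(empty)
  expect_warning(out <- read_dotbracket_file(empty), "empty")
  expect_equal(out, list())
})

test_that("deduplication removes exact copies always, near-copies on request", {
  recs <- make_records(c("((...))", ".....", "(((...)))"))
  recs <- c(recs, recs[1])  # exact duplicate
  out <- remove_redundant(recs)
  expect_equal(length(out), 3L)
  # two sequences differing at 4 of 100 positions: identity 96%
  st <- random_structure(100, min_loop = 3, pair_density = 0, seed = 5)
  a <- sequence_for_structure(st, seed = 6, id = "a")
  bases <- strsplit(a$bases, "")[[1]]
  flip <- c(10, 35, 60, 85)
  bases[flip] <- vapply(bases[flip], function(b)
    setdiff(c("A", "U", "G", "C"), b)[1], character(1))
  b <- rna_sequence(paste(bases, collapse = ""), id = "b")
  pair <- list(dataset_record(a, st), dataset_record(b, st))
  expect_equal(length(remove_redundant(pair, 0.95)), 1L)
  expect_equal(length(remove_redundant(pair, 0.99)), 2L)
  expect_equal(length(remove_redundant(pair, 1.0)), 2L)
})

test_that("pseudoknot filtering keeps exactly the nested records, idempotently", {
  nested <- make_records(c("((...))", ".....", "(...)"))
  crossed <- lapply(1:2, function(i) {
    st <- rna_structure(rbind(c(1, 6), c(4, 9)), 10)
    s <- rna_sequence("GAAGCAUCAC", id = paste0("pk", i))
    dataset_record(s, st, family = "fam")
  })
  expect_true(crossed[[1]]$structure$pseudoknotted)
  mixed <- c(nested, crossed)
  kept <- filter_pseudoknots(mixed, quiet = TRUE)
  expect_equal(length(kept), 3L)
  expect_identical(filter_pseudoknots(kept, quiet = TRUE), kept)
  expect_equal(filter_pseudoknots(list(), quiet = TRUE), list())
  expect_message(filter_pseudoknots(mixed), "5 before, 3 after")
})

test_that("dataset splitting honours 7:2:1 and partitions the input", {
  recs100 <- make_records(rep(c("((...))", "....."), 50))
  sp <- split_dataset(recs100, seed = 3)
  expect_equal(vapply(sp, length, integer(1)),
               c(train = 70L, validation = 20L, test = 10L))
  recs10 <- make_records(rep("(...)", 10))
  sp10 <- split_dataset(recs10, seed = 3)
  expect_equal(vapply(sp10, length, integer(1)),
               c(train = 7L, validation = 2L, test = 1L))
  # partition property under several seeds
  ids <- function(rs) sort(vapply(rs, function(r) r$seq$id, character(1)))
  recs <- make_records(rep(c("((...))", ".....", "(...)"), 9))
  for (seed in 1:4) {
    sp <- split_dataset(recs, seed = seed)
    all_ids <- c(ids(sp$train), ids(sp$validation), ids(sp$test))
    expect_equal(sort(all_ids), ids(recs))
    expect_equal(anyDuplicated(all_ids), 0L)
  }
  expect_identical(lapply(split_dataset(recs, seed = 7), ids),
                   lapply(split_dataset(recs, seed = 7), ids))
  expect_error(split_dataset(recs[1:2]), "at least 3")
})

test_that("stratified splits keep family proportions", {
  fam_a <- make_records(rep("(...)", 20), family = "a")
  fam_b <- make_records(rep("((...))", 10), family = "b")
  sp <- split_dataset(c(fam_a, fam_b), seed = 1, stratify_by_family = TRUE)
  fams <- function(rs) table(vapply(rs, function(r) r$family, character(1)))
  expect_equal(unname(fams(sp$train)["a"]), 14L)
  expect_equal(unname(fams(sp$train)["b"]), 7L)
  expect_equal(unname(fams(sp$test)["a"]), 2L)
  expect_equal(unname(fams(sp$test)["b"]), 1L)
})

test_that("dataset statistics find the longest stacked run and mean length", {
  one <- make_records("((..))")
  st1 <- dataset_stats(one)
  expect_equal(st1$max_stem_length, 2L)
  expect_equal(st1$mean_sequence_length, 6L)
  expect_equal(dataset_stats(make_records("(...)"))$max_stem_length, 1L)
  # bulges break stems: ((((...)))).((...)) has runs of 4 and 2
  multi <- make_records("((((...)))).((...))")
  expect_equal(dataset_stats(multi)$max_stem_length, 4L)
  # planted hairpin ground truth
  planted <- list(hairpin_record(7, 4), hairpin_record(3, 5))
  expect_equal(dataset_stats(planted)$max_stem_length, 7L)
  expect_equal(dataset_stats(planted)$mean_sequence_length,
               as.integer(round(mean(c(18, 11)))))
})
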