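toy_dataset <- function(id = 1L, n = 3L, promoter = "toy", ref = "R1") {
  set.seed(100 + id)
  recs <- data.frame(
    variant_label = c("WT", paste0("m", seq_len(n - 1L))),
    is_wildtype = c(TRUE, rep(FALSE, n - 1L)),
    seq = vapply(seq_len(n), function(i) rand_dna(90L), character(1)),
    expression = stats::rnorm(n, 5),
    species_tag = "ntTBP", exp_condition = "toy",
    predicted_minus_ln_kd = stats::rnorm(n, 20),
    reference = ref, stringsAsFactors = FALSE)
  tata_dataset(id, promoter, "reporter", "toy system", "ntTBP", "II", recs)
}

test_that("write_kb then read_kb restores the datasets (round trip)", {
  kb <- list(toy_dataset(1L, 3L), toy_dataset(2L, 5L, promoter = "toy2"))
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))
  write_kb(kb, tmp)
  back <- read_kb(tmp)
  expect_length(back, 2L)
  for (i in 1:2) {
    expect_equal(back[[i]]$dataset_id, kb[[i]]$dataset_id)
    expect_equal(back[[i]]$promoter_name, kb[[i]]$promoter_name)
    expect_equal(back[[i]]$n_variants, kb[[i]]$n_variants)
    expect_equal(back[[i]]$records$seq, kb[[i]]$records$seq)
    expect_equal(back[[i]]$records$is_wildtype, kb[[i]]$records$is_wildtype)
    expect_equal(back[[i]]$records$expression, kb[[i]]$records$expression,
                 tolerance = 1e-12)
  }
})

test_that("a toy 3-row file yields one dataset with three variants", {
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))
  write_kb(list(toy_dataset(7L, 3L)), tmp)
  kb <- read_kb(tmp)
  expect_length(kb, 1L)
  expect_equal(kb[[1]]$n_variants, 3L)
  expect_equal(kb[[1]]$dataset_id, 7L)
})

test_that("malformed rows are dropped with line-numbered diagnostics", {
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))
  write_kb(list(toy_dataset(1L, 5L)), tmp)
  lines <- readLines(tmp)
  # corrupt data rows 2 and 4 (file lines 3 and 5): bad expression, bad base
  f2 <- strsplit(lines[3], "\t")[[1]]; f2[10] <- "not-a-number"
  f4 <- strsplit(lines[5], "\t")[[1]]; f4[9] <- "ACGTNACGT"
  lines[3] <- paste(f2, collapse = "\t")
  lines[5] <- paste(f4, collapse = "\t")
  writeLines(lines, tmp)
  expect_warning(kb <- read_kb(tmp), "2 malformed row")
  probs <- attr(kb, "problems")
  expect_equal(sort(probs$line), c(3L, 5L))
  expect_match(probs$message[probs$line == 3L], "non-numeric expression")
  expect_match(probs$message[probs$line == 5L], "invalid base")
  expect_equal(kb[[1]]$n_variants, 3L)
})

test_that("missing columns and empty files are hard errors", {
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))
  file.create(tmp)
  expect_error(read_kb(tmp), "empty")
  writeLines("dataset_id\tseq", tmp)
  expect_error(read_kb(tmp), "missing columns")
  expect_error(read_kb(tempfile()), "not found")
})

test_that("embedded delimiters are rejected by the flat-file dialect", {
  d <- toy_dataset(1L, 3L)
  d$records$exp_condition[2] <- "has\ttab"
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))
  expect_error(write_kb(list(d), tmp), "embedded delimiter")
})

test_that("an empty collection writes a header-only file", {
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))
  write_kb(list(), tmp)
  lines <- readLines(tmp)
  expect_length(lines, 1L)
  expect_match(lines, "^dataset_id\t")
  expect_length(read_kb(tmp), 0L)
})

test_that("a single 5-record dataset summarizes to unit distinct counts", {
  s <- summarize_kb(list(toy_dataset(1L, 5L)))
  expect_equal(
    c(s$n_promoters, s$n_genes, s$n_systems, s$n_tbps, s$n_pols,
      s$n_variants, s$n_references),
    c(1L, 1L, 1L, 1L, 1L, 5L, 1L))
})

test_that("the compilation-shaped fixture reproduces the TOTAL bookkeeping", {
  kb <- kb_table1_fixture(seed = 17L)
  counts <- vapply(kb, `[[`, integer(1), "n_variants")
  expect_equal(counts, c(24L, 24L, 8L, 16L, 30L, 7L, 7L, 7L, 10L, 5L, 52L, 52L))
  s <- summarize_kb(kb)
  expect_equal(s$n_variants, 242L)
  expect_equal(s$n_promoters, 10L)
  expect_equal(s$n_genes, 7L)
  expect_equal(s$n_systems, 6L)
  expect_equal(s$n_tbps, 4L)
  expect_equal(s$n_pols, 2L)
  expect_equal(s$n_references, 9L)
  # totals equal an independent exhaustive recount
  expect_equal(s$n_variants, sum(vapply(kb, function(d) nrow(d$records), integer(1))))
})

test_that("summarize_kb is invariant under dataset and record permutation", {
  kb <- list(toy_dataset(1L, 5L), toy_dataset(2L, 7L, promoter = "p2", ref = "R2"),
             toy_dataset(3L, 6L, ref = "R1,R3"))
  shuffled <- kb[c(3, 1, 2)]
  shuffled <- lapply(shuffled, function(d) {
    d$records <- d$records[sample(nrow(d$records)), ]
    d
  })
  expect_equal(unclass(summarize_kb(kb)), unclass(summarize_kb(shuffled)))
})

test_that("FASTA export carries every variant with a composite id", {
  kb <- list(toy_dataset(1L, 3L), toy_dataset(2L, 5L))
  tmp <- tempfile(fileext = ".fasta")
  on.exit(unlink(tmp))
  export_kb_fasta(kb, tmp)
  set <- Biostrings::readDNAStringSet(tmp)
  expect_length(set, 8L)
  expect_true(all(grepl("^ds[12]\\|", names(set))))
})
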