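test_that("promoter validation normalizes case, maps U to T, and flags length", {
  p <- validate_promoter(strrep("acgt", 22L), id = "lc", expected_length = 88)
  expect_s3_class(p, "PromoterSequence")
  expect_equal(p$length, 88L)
  expect_equal(p$seq, strrep("ACGT", 22L))
  expect_false(p$nonstandard_length)

  p2 <- suppressWarnings(validate_promoter("uuacgu", expected_length = NULL))
  expect_equal(p2$seq, "TTACGT")

  expect_warning(validate_promoter(strrep("ACGT", 22L), id = "short88"),
                 "88 bp")
  p3 <- suppressWarnings(validate_promoter(strrep("ACGT", 22L)))
  expect_true(p3$nonstandard_length)
})

test_that("invalid characters are rejected with their position", {
  expect_error(validate_promoter("ACGNACGT", id = "bad"),
               "invalid base 'N' at position 4")
  expect_error(validate_promoter("   ", id = "blank"), "empty")
})

test_that("sequences shorter than the window are refused at scan time", {
  m <- affinity_model()
  p <- suppressWarnings(validate_promoter(strrep("AC", 7L),
                                          expected_length = NULL))
  expect_error(window_scores(p, m), "shorter than the 15 bp")
})

test_that("window counts follow length - window_w + 1 per strand", {
  p <- quiet_promoter(consensus_promoter())
  m1 <- affinity_model(scan_both_strands = FALSE)
  m2 <- affinity_model(scan_both_strands = TRUE)
  ws1 <- window_scores(p, m1)
  ws2 <- window_scores(p, m2)
  expect_equal(nrow(ws1), 90L - 15L + 1L)
  expect_equal(nrow(ws2), 2L * (90L - 15L + 1L))
  expect_true(all(diff(ws1$start) == 1L))
  expect_setequal(unique(ws2$strand), c("+", "-"))
})

test_that("a consensus-bearing window attains the column-wise PWM maximum", {
  m <- affinity_model()
  p <- quiet_promoter(consensus_promoter(offset = 43L))
  ws <- window_scores(p, m)
  attainable_max <- sum(apply(m$pwm, 2, max))
  expect_equal(max(ws$stop_score), attainable_max)
  # the maximum sits on a window whose core is the planted consensus
  best <- ws[which.max(ws$stop_score), ]
  expect_match(best$window, "TCACTATATATAG")
})

test_that("window scores match a brute-force per-position oracle", {
  set.seed(101)
  m <- affinity_model()
  for (rep in 1:3) {
    seq <- rand_dna(90L)
    ws <- window_scores(quiet_promoter(seq), m)
    orc <- oracle_windows(seq, m)
    expect_equal(ws$stop_score, unname(orc[, "stop_score"]))
    expect_equal(ws$slide_score, unname(orc[, "slide_score"]))
    expect_equal(ws$bend_score, unname(orc[, "bend_score"]))
  }
})

test_that("estimate_affinity recombines slide/stop/bend per the model formula", {
  set.seed(202)
  m <- affinity_model(c0 = 0.3, c1 = 1.2, c2 = 0.8, c3 = 1.5, epsilon = 0.4)
  for (rep in 1:5) {
    seq <- rand_dna(90L)
    est <- estimate_affinity(quiet_promoter(seq), m)
    orc <- oracle_windows(seq, m)
    stop_c <- max(orc[, "stop_score"])
    # oracle recombination: slide averaged over all windows, bend of argmax
    best_rows <- orc[orc[, "stop_score"] == stop_c, , drop = FALSE]
    expect_equal(est$components[["stop"]], stop_c)
    expect_equal(est$components[["slide"]], mean(orc[, "slide_score"]))
    expect_true(any(abs(best_rows[, "bend_score"] -
                          est$components[["bend"]]) < 1e-9))
    expect_equal(est$minus_ln_kd,
                 0.3 + 1.2 * est$components[["slide"]] +
                   0.8 * est$components[["stop"]] +
                   1.5 * est$components[["bend"]])
    expect_equal(est$sd, 0.4)
  }
})

test_that("identical inputs give bit-identical estimates", {
  m <- affinity_model()
  p <- quiet_promoter(consensus_promoter())
  expect_identical(estimate_affinity(p, m), estimate_affinity(p, m))
})

test_that("both-strand scanning is invariant under reverse complement", {
  m <- affinity_model(scan_both_strands = TRUE)
  set.seed(303)
  for (rep in 1:10) {
    seq <- rand_dna(90L)
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
    e1 <- estimate_affinity(quiet_promoter(seq), m)
    e2 <- estimate_affinity(quiet_promoter(rc), m)
    expect_equal(e1$minus_ln_kd, e2$minus_ln_kd)
    expect_equal(e1$components, e2$components)
  }
})

test_that("model parameter validation enforces shape and positivity", {
  expect_error(affinity_model(epsilon = 0), "positive")
  expect_error(affinity_model(pwm = matrix(0, 3, 15)), "4-row")
  expect_error(affinity_model(window_w = 14L, pwm = pwm_from_consensus(window_w = 15L)),
               "columns")
  expect_error(affinity_model(slide_scale = numeric(0)), "16 dinucleotides")
})

test_that("shipped PWM file equals the consensus builder and round-trips", {
  shipped <- read_pwm(system.file("extdata", "tata_pwm.tsv",
                                  package = "planttata"))
  expect_equal(shipped, pwm_from_consensus(), tolerance = 1e-12)
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))
  write_pwm(shipped, tmp)
  expect_equal(read_pwm(tmp), shipped, tolerance = 1e-12)
})

test_that("the shipped config file reproduces the default parameterization", {
  cfg <- read_model_config(system.file("extdata", "default_model.tsv",
                                       package = "planttata"))
  expect_equal(cfg$model$pwm, pwm_from_consensus(), tolerance = 1e-12)
  expect_equal(cfg$model$window_w, 15L)
  expect_equal(cfg$model$epsilon, 0.5)
  expect_equal(cfg$rescale$a1, 1.1)
  expect_equal(cfg$rescale$b2, 0.6)
  expect_equal(cfg$alpha, 0.05)
  p <- quiet_promoter(consensus_promoter())
  expect_equal(estimate_affinity(p, cfg$model)$minus_ln_kd,
               estimate_affinity(p, affinity_model())$minus_ln_kd)
})
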