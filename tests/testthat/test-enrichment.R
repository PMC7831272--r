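test_that("PWM construction validates and clamps probabilities", {
  m <- matrix(0.25, 8, 4)
  expect_s3_class(pwm(m), "pwm")
  expect_error(pwm(m[, 1:3]), "4 columns")
  expect_error(pwm(m[1:3, ]), "length >= 4")
  bad <- m; bad[1, ] <- c(0.5, 0.5, 0.5, 0.5)
  expect_error(pwm(bad), "sum to 1")
  # zero probabilities are clamped away from -Inf log-odds
  z <- matrix(c(1, 0, 0, 0), 8, 4, byrow = TRUE)
  pz <- pwm(z)
  expect_true(all(pz$mat > 0))
})

test_that("bundled JASPAR-style PWM text round-trips through read_pwms", {
  path <- system.file("extdata", "pwms.txt", package = "acetylink")
  pwms <- read_pwms(path)
  expect_length(pwms, 4)
  expect_named(pwms, c("planted", "decoy_ttgacc", "decoy_ggatcc", "decoy_caacgg"))
  expect_equal(nrow(pwms$planted$mat), 10)
  expect_equal(rowSums(pwms$planted$mat), rep(1, 10), tolerance = 1e-9)
  # consensus of the planted motif
  cons <- paste(c("A", "C", "G", "T")[apply(pwms$planted$mat, 1, which.max)],
                collapse = "")
  expect_equal(cons, "ACGTCATGCA")
})

test_that("PWM scanning scores log-odds against the maximum achievable", {
  # 0.5 on consensus, 1/6 off: consensus window scores L * log2(0.5/0.25)
  L <- 8
  m <- matrix(1 / 6, L, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  m[cbind(1:L, rep(1, L))] <- 0.5  # consensus AAAAAAAA
  p <- pwm(m, "halfmax")
  hits <- scan_pwm(strrep("A", L), p)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$score, L * log2(0.5 / 0.25), tolerance = 1e-6)
  expect_equal(hits$position, 0)
  # shorter sequence than the motif -> empty hit list
  expect_equal(nrow(scan_pwm("ACGT", p)), 0)
  # windows containing N are skipped
  expect_equal(nrow(scan_pwm(paste0(strrep("A", 4), "N", strrep("A", 4)), p)), 0)
  # uniform PWM is zero-information: flagged unscannable
  u <- pwm(matrix(0.25, 8, 4), "flat")
  expect_warning(h <- scan_pwm(strrep("A", 20), u), "unscannable")
  expect_true(attr(h, "unscannable"))
  expect_equal(nrow(h), 0)
})

test_that("PWM scanning is strand-symmetric", {
  pwms <- read_pwms(system.file("extdata", "pwms.txt", package = "acetylink"))
  set.seed(17)
  for (i in 1:25) {
    s <- random_seq(300)
    if (i %% 3 == 0) {
      pos <- sample(290, 1)
      substr(s, pos, pos + 9) <- "ACGTCATGCA"
    }
    expect_equal(nrow(scan_pwm(s, pwms$planted)),
                 nrow(scan_pwm(revcomp(s), pwms$planted)))
  }
})

test_that("hypergeometric enrichment matches exact enumeration", {
  # universe of 20 sequences, 5 with motif; target 5 of which 3 carry it
  expect_equal(acetylink:::hypergeom_upper(3, 5, 20, 5),
               hyper_tail_oracle(3, 5, 20, 5), tolerance = 1e-12)
  expect_equal(acetylink:::hypergeom_upper(3, 5, 20, 5), 0.0726, tolerance = 1e-3)
  # extreme case: all targets carry it, no background does
  expect_equal(acetylink:::hypergeom_upper(5, 5, 20, 5), 1 / choose(20, 5),
               tolerance = 1e-12)
  # p is monotone non-increasing in overlap
  ps <- sapply(0:5, function(k) acetylink:::hypergeom_upper(k, 8, 30, 5))
  expect_true(all(diff(ps) <= 1e-15))
})

test_that("motif enrichment counts sequences with hits and tests the target draw", {
  p <- read_pwms(system.file("extdata", "pwms.txt", package = "acetylink"))$planted
  set.seed(23)
  with_motif <- vapply(1:6, function(i) {
    s <- random_seq(200); substr(s, 50, 59) <- "ACGTCATGCA"; s
  }, "")
  without <- vapply(1:14, function(i) random_seq(200), "")
  target <- c(with_motif[1:5], without[1])
  background <- c(with_motif[6], without[2:14])
  res <- motif_enrichment(target, background, p)
  expect_equal(res$overlap, 5)
  expect_equal(res$frac_targets, 5 / 6)
  expect_equal(res$p, hyper_tail_oracle(5, res$set_size, 20, 6),
               tolerance = 1e-12)
  expect_error(motif_enrichment(character(0), without, p), "empty target")
})

test_that("gene-set ORA matches the exact tail and ranks a fully hit set first", {
  universe <- paste0("g", 1:20)
  sets <- list(hit = paste0("g", 1:5),
               other = paste0("g", 6:10),
               third = paste0("g", 11:15))
  res <- geneset_enrichment(paste0("g", c(1:3, 16, 17)), universe, sets)
  expect_equal(res$p[res$name == "hit"], hyper_tail_oracle(3, 5, 20, 5),
               tolerance = 1e-12)
  expect_equal(res$name[1], "hit")
  # query equal to one full set, disjoint from the others, ranks it first
  res2 <- geneset_enrichment(sets$hit, universe, sets)
  expect_equal(res2$name[1], "hit")
  expect_equal(res2$overlap[1], 5)
  # query genes outside the universe are dropped with a message
  expect_message(geneset_enrichment(c("g1", "absent"), universe, sets), "dropped")
  expect_error(geneset_enrichment("g1", character(0), sets), "empty gene universe")
})

test_that("random queries are not systematically enriched", {
  set.seed(41)
  universe <- paste0("g", 1:1000)
  sets <- lapply(1:60, function(i) sample(universe, 50))
  names(sets) <- paste0("set", 1:60)
  rates <- replicate(10, {
    res <- geneset_enrichment(sample(universe, 100), universe, sets)
    mean(res$p < 0.05)
  })
  # hypergeometric null: close to (and discretely below) the nominal 5%
  expect_lt(mean(rates), 0.09)
  expect_gt(mean(rates), 0.005)
})

test_that("GMT files round-trip", {
  sets <- list(a = c("g1", "g2"), b = c("g3", "g4", "g5"))
  path <- tempfile(fileext = ".gmt")
  write_gmt(sets, path)
  expect_equal(read_gmt(path), sets)
})
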