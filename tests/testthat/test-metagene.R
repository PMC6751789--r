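test_that("top contributors flags injected outliers by sign", {
  set.seed(41)
  s <- c(rnorm(1000), inj_hi = 10, inj_lo = -12)
  names(s)[1:1000] <- paste0("g", 1:1000)
  sig <- top_contributors(s, alpha = 0.01)
  expect_true("inj_hi" %in% sig$positive$feature_id)
  expect_true("inj_lo" %in% sig$negative$feature_id)
  expect_length(intersect(sig$positive$feature_id,
                          sig$negative$feature_id), 0)
  expect_true(all(sig$positive$adj_p < 0.01))
  expect_error(top_contributors(rep(1, 100)), "MAD")
  expect_error(top_contributors(rnorm(5)), "length")
})

test_that("top contributors is calibrated under the global null", {
  flagged <- vapply(1:50, function(seed) {
    set.seed(seed)
    s <- setNames(rnorm(5000), paste0("g", 1:5000))
    sig <- top_contributors(s, alpha = 0.01)
    nrow(sig$positive) + nrow(sig$negative)
  }, numeric(1))
  expect_lte(mean(flagged), 0.5)
})

test_that("z-scores are invariant to positive rescaling of the metagene", {
  set.seed(42)
  s <- setNames(c(rnorm(500), 8, -9), paste0("g", 1:502))
  a <- top_contributors(s)
  b <- top_contributors(s * 37.5)
  expect_identical(a$positive$feature_id, b$positive$feature_id)
  expect_equal(a$positive$z, b$positive$z, tolerance = 1e-12)
  expect_equal(a$negative$adj_p, b$negative$adj_p, tolerance = 1e-12)
})

test_that("BH adjustment matches the hand-computed and brute-force rule", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03)),
               c(0.03, 0.03, 0.03))
  expect_equal(benjamini_hochberg(0.2), 0.2)
  set.seed(43)
  for (rep in 1:50) {
    p <- runif(sample(1:20, 1))
    expect_equal(benjamini_hochberg(p), bh_oracle(p), tolerance = 1e-12)
  }
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "within")
  expect_error(benjamini_hochberg(c(0.5, NA)), "within")
})

test_that("orientation flips heavy-negative components, preserving S %*% M", {
  set.seed(44)
  n <- 600
  S <- cbind(c(rnorm(n - 45), -seq(8, 12, length.out = 40), seq(8, 10,
                                                                length.out = 5)),
             c(rnorm(n - 10), seq(8, 12, length.out = 10)))
  rownames(S) <- paste0("g", 1:n)
  colnames(S) <- c("IC1", "IC2")
  M <- matrix(rnorm(2 * 30), 2, 30,
              dimnames = list(colnames(S), paste0("s", 1:30)))
  fit <- fake_fit(M, S = S)
  prod0 <- fit$S %*% fit$M
  or1 <- orient_components(fit)
  expect_identical(attr(or1, "flipped"), c(TRUE, FALSE))
  expect_equal(or1$S %*% or1$M, prod0, tolerance = 1e-12)
  # idempotent
  or2 <- orient_components(or1)
  expect_identical(attr(or2, "flipped"), c(FALSE, FALSE))
  expect_identical(or2$S, or1$S)
})

test_that("orientation honours supplied enrichment results", {
  set.seed(45)
  S <- named_mat(c(rnorm(98), 9, -9), 100, 1)
  colnames(S) <- "IC1"
  M <- matrix(rnorm(20), 1, 20,
              dimnames = list("IC1", paste0("s", 1:20)))
  fit <- fake_fit(M, S = S)
  enr <- list(list(best_p_positive = 0.5, best_p_negative = 1e-6))
  flipped <- orient_components(fit, enrichment = enr)
  expect_true(attr(flipped, "flipped"))
  expect_equal(flipped$S, -S)
})

test_that("miRNA components flip only on strong negative mRNA correlation", {
  set.seed(46)
  m <- 200
  Mr <- named_mat(rnorm(3 * m), 3, m, fprefix = "IC")
  Mm <- rbind(-Mr[1, ],                                  # r = -1: flip
              0.3 * Mr[2, ] + rnorm(m),                  # weak: keep
              rnorm(m))                                  # unrelated: keep
  dimnames(Mm) <- list(paste0("IC", 1:3), colnames(Mr))
  fa <- fake_fit(Mm); fb <- fake_fit(Mr)
  out <- orient_mirna_by_link(fa, fb, threshold = 0.5)
  expect_identical(attr(out, "flipped"), c(TRUE, FALSE, FALSE))
  expect_gt(cor(out$M[1, ], Mr[1, ]), 0.99)

  # null behaviour: independent weights almost never flip
  flips <- vapply(1:40, function(seed) {
    set.seed(seed + 1000)
    fa <- fake_fit(named_mat(rnorm(2 * m), 2, m, fprefix = "A"))
    fb <- fake_fit(named_mat(rnorm(2 * m), 2, m, fprefix = "B"))
    sum(attr(orient_mirna_by_link(fa, fb, 0.5), "flipped"))
  }, numeric(1))
  expect_lte(mean(flips > 0), 0.05)

  fc <- fake_fit(matrix(rnorm(4), 2, 2,
                        dimnames = list(c("IC1", "IC2"), c("x1", "x2"))))
  expect_error(orient_mirna_by_link(fa, fc), "shared samples")
})

test_that("hypergeometric enrichment matches closed forms and enumeration", {
  bg <- paste0("g", 1:10)
  expect_equal(hypergeometric_enrichment(bg, bg, bg), 1)

  bg20 <- paste0("g", 1:20)
  gs <- bg20[1:5]
  expect_equal(hypergeometric_enrichment(bg20[1:5], gs, bg20),
               1 / choose(20, 5), tolerance = 1e-12)

  set.seed(47)
  for (rep in 1:20) {
    N <- sample(5:12, 1)
    bgN <- paste0("g", seq_len(N))
    gs <- sample(bgN, sample(1:N, 1))
    sg <- sample(bgN, sample(1:(N - 1), 1))
    expect_equal(hypergeometric_enrichment(sg, gs, bgN),
                 hyper_oracle(sg, gs, bgN), tolerance = 1e-12)
  }
  expect_error(hypergeometric_enrichment("a", "a", character(0)),
               "empty background")
})

test_that("signature matching selects the right reference profile", {
  set.seed(48)
  n <- 200
  R <- qr.Q(qr(matrix(rnorm(n * 5), n, 5))) * sqrt(n)  # unit-variance profiles
  dimnames(R) <- list(paste0("g", 1:n), paste0("cell", 1:5))
  S <- cbind(IC1 = R[, 3] + rnorm(n, sd = 0.1), IC2 = -R[, 5])
  rownames(S) <- rownames(R)
  M <- matrix(rnorm(2 * 10), 2, 10,
              dimnames = list(colnames(S), paste0("s", 1:10)))
  fit <- fake_fit(M, S = S)
  bm <- best_signature_match(fit, R)
  expect_identical(bm$match, c("cell3", "cell5"))
  expect_gt(bm$r[1], 0.9)
  expect_lt(bm$r[2], -0.99)
  expect_error(best_signature_match(fit, R[1:2, , drop = FALSE]),
               "shared features")
})

test_that("GMT reading and enrichment table work end to end", {
  f <- tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tg1\tg2\tg3",
               "setB\tna\tg4\tg5\tg6\tg7"), f)
  sets <- read_gmt(f)
  expect_named(sets, c("setA", "setB"))
  expect_identical(sets$setA, c("g1", "g2", "g3"))

  bg <- paste0("g", 1:30)
  tab <- enrich_signature(c("g1", "g2", "g3"), sets, bg)
  expect_identical(tab$set[1], "setA")
  expect_true(all(tab$adj_p >= tab$p))
})
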