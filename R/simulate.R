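#' Define a synthetic mixture scenario
#'
#' Bundles the parameters of the generative model the decomposition assumes:
#' `k_true` mutually independent non-Gaussian source signals (metagenes)
#' mixed into `m` bulk samples by a random mixing matrix, plus Gaussian
#' measurement noise and, optionally, an additive per-feature offset on one
#' block of samples emulating the technical shift between a large discovery
#' cohort and a small investigation cohort measured on a different platform.
#'
#' @param n features. @param m samples. @param k_true number of sources.
#' @param source one of `"laplace"` (scale-1 Laplace, the simplest
#'   super-Gaussian family satisfying ICA identifiability) or
#'   `"sparse_spike"` (mostly zero with a few large positive loadings,
#'   mimicking cell-type marker metagenes).
#' @param sparsity fraction of non-zero loadings for the sparse-spike
#'   family.
#' @param noise_sd sd of additive Gaussian noise (default 0.1).
#' @param batch_size number of samples in the second ("investigation")
#'   block; 0 disables the batch effect.
#' @param batch_sd sd of the per-feature additive offset applied to the
#'   batch block.
#' @param seed integer seed.
#' @return list of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(n = 2000L, m = 100L, k_true = 5L,
                               source = c("laplace", "sparse_spike"),
                               sparsity = 0.05, noise_sd = 0.1,
                               batch_size = 0L, batch_sd = 0,
                               seed = 1L) {
  source <- match.arg(source)
  if (k_true >= min(n, m)) stop("k_true must be < min(n, m)")
  if (batch_size >= m) stop("batch block must be smaller than m")
  structure(list(n = as.integer(n), m = as.integer(m),
                 k_true = as.integer(k_true), source = source,
                 sparsity = sparsity, noise_sd = noise_sd,
                 batch_size = as.integer(batch_size), batch_sd = batch_sd,
                 seed = as.integer(seed)),
            class = "synthetic_scenario")
}

rlaplace <- function(n) {
  u <- stats::runif(n, -0.5, 0.5)
  -sign(u) * log(1 - 2 * abs(u))
}

#' Simulate an expression matrix with known sources
#'
#' Draws `S_true` (n x k) from the scenario's super-Gaussian family,
#' `M_true` (k x m) from a standard normal, and returns
#' `E = S_true %*% M_true + noise + batch offsets` together with the ground
#' truth. Deterministic given the scenario seed. The last `batch_size`
#' samples form the "investigation" block and receive the per-feature
#' offset.
#'
#' @param scn a `synthetic_scenario`.
#' @return list: `E` (`expr_matrix`, scale `log2`), `S_true`, `M_true`,
#'   `batch` (data.frame sample_id, batch), `scenario`.
#' @export
simulate_mixture <- function(scn) {
  stopifnot(inherits(scn, "synthetic_scenario"))
  set.seed(scn$seed)
  S <- switch(scn$source,
    laplace = matrix(rlaplace(scn$n * scn$k_true), scn$n, scn$k_true),
    sparse_spike = {
      s <- matrix(0, scn$n, scn$k_true)
      nz <- max(1L, round(scn$sparsity * scn$n))
      for (i in seq_len(scn$k_true)) {
        idx <- sample.int(scn$n, nz)
        s[idx, i] <- abs(stats::rnorm(nz, mean = 3))
      }
      s
    })
  M <- matrix(stats::rnorm(scn$k_true * scn$m), scn$k_true, scn$m)
  E <- S %*% M
  if (scn$noise_sd > 0)
    E <- E + matrix(stats::rnorm(scn$n * scn$m, sd = scn$noise_sd),
                    scn$n, scn$m)
  batch <- rep(c("discovery", "investigation"),
               c(scn$m - scn$batch_size, scn$batch_size))
  if (scn$batch_size > 0L && scn$batch_sd > 0) {
    off <- stats::rnorm(scn$n, sd = scn$batch_sd)
    E[, batch == "investigation"] <- E[, batch == "investigation"] + off
  }
  fid <- sprintf("g%04d", seq_len(scn$n))
  sid <- sprintf("s%03d", seq_len(scn$m))
  dimnames(E) <- list(fid, sid)
  dimnames(S) <- list(fid, paste0("src", seq_len(scn$k_true)))
  dimnames(M) <- list(paste0("src", seq_len(scn$k_true)), sid)
  list(E = expr_matrix(E, scale = "log2"), S_true = S, M_true = M,
       batch = data.frame(sample_id = sid, batch = batch,
                          stringsAsFactors = FALSE),
       scenario = scn)
}

#' Simulate survival driven by one component's weights
#'
#' Event times are exponential with hazard
#' `baseline * exp(beta * w_std)`, where `w_std` is the standardised weight
#' row of the driver component. Censoring is uniform on `(0, T_max)` with
#' `T_max` tuned by bisection so the realised censoring fraction matches the
#' request to within ±0.05 in expectation.
#'
#' @param M_true k x m weight matrix.
#' @param driver index of the hazard-driving component.
#' @param beta log-hazard ratio per sd of weight (default 1).
#' @param baseline baseline hazard rate (default 0.01 per day).
#' @param censor_frac requested censoring fraction in [0, 1).
#' @param seed integer seed.
#' @return data.frame (sample_id, time, event).
#' @export
simulate_survival <- function(M_true, driver = 1L, beta = 1, baseline = 0.01,
                              censor_frac = 0.3, seed = 1L) {
  if (driver < 1L || driver > nrow(M_true)) stop("invalid driver index")
  if (censor_frac < 0 || censor_frac >= 1) stop("censor_frac must be in [0, 1)")
  set.seed(seed)
  w <- as.vector(scale(M_true[driver, ]))
  m <- length(w)
  haz <- baseline * exp(beta * w)
  t_event <- stats::rexp(m, rate = haz)
  if (censor_frac == 0) {
    time <- t_event; event <- rep(1L, m)
  } else {
    # E[censored] for uniform(0, Tmax) censoring: mean P(C < T)
    frac <- function(tmax) {
      p <- (1 - exp(-haz * tmax)) / (haz * tmax)  # P(C < T | haz)
      mean(p)
    }
    lo <- 1e-6; hi <- 1
    while (frac(hi) > censor_frac) hi <- hi * 2
    for (it in 1:60) {
      mid <- (lo + hi) / 2
      if (frac(mid) > censor_frac) lo <- mid else hi <- mid
    }
    t_cens <- stats::runif(m, 0, hi)
    event <- as.integer(t_event <= t_cens)
    time <- pmin(t_event, t_cens)
  }
  data.frame(sample_id = colnames(M_true), time = time, event = event,
             stringsAsFactors = FALSE)
}

#' Simulate class labels driven by one component's weights
#'
#' @param M_true k x m weight matrix.
#' @param driver component index.
#' @param rule `"sign"` (two classes by sign of the weight) or `"tertile"`
#'   (three classes by weight tertile).
#' @param noise_frac fraction of labels replaced by a uniformly drawn class
#'   (0 = noiseless).
#' @param seed integer seed.
#' @return factor of length m, named by sample id.
#' @export
simulate_labels <- function(M_true, driver = 1L, rule = c("sign", "tertile"),
                            noise_frac = 0, seed = 1L) {
  rule <- match.arg(rule)
  if (driver < 1L || driver > nrow(M_true)) stop("invalid driver index")
  w <- M_true[driver, ]
  lab <- switch(rule,
    sign = factor(ifelse(w > 0, "pos", "neg"), levels = c("neg", "pos")),
    tertile = cut(rank(w, ties.method = "first"),
                  breaks = 3, labels = c("low", "mid", "high")))
  if (noise_frac > 0) {
    set.seed(seed)
    flip <- stats::runif(length(lab)) < noise_frac
    lab[flip] <- sample(levels(lab), sum(flip), replace = TRUE)
  }
  stats::setNames(lab, colnames(M_true))
}
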