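#' Per-component Cox survival screen
#'
#' Fits one univariable Cox proportional-hazards model per component weight
#' row (standardised to zero mean, unit sd, so the log-hazard ratios are per
#' standard deviation of weight and comparable across components). The
#' log-rank (score) test p-value is Benjamini-Hochberg adjusted across the
#' k components.
#'
#' @param fit a `consica` object, or a bare k x m weight matrix with
#'   component row names and sample column names.
#' @param surv data.frame with columns `sample_id`, `time` (> 0) and
#'   `event` (1 = event observed, 0 = censored). Samples are matched to
#'   weight columns by id; samples without weights are dropped.
#' @return data.frame of class `component_survival`:
#'   component, LHR, se, p (log-rank), adj_p.
#' @export
cox_per_component <- function(fit, surv) {
  M <- if (inherits(fit, "consica")) fit$M else fit
  req <- c("sample_id", "time", "event")
  if (!all(req %in% names(surv))) stop("surv needs columns sample_id, time, event")
  if (any(surv$time <= 0)) stop("survival times must be > 0")
  surv <- surv[surv$sample_id %in% colnames(M), , drop = FALSE]
  if (sum(surv$event) < 2L) stop("need at least 2 observed events")
  M <- M[, surv$sample_id, drop = FALSE]
  ss <- survival::Surv(surv$time, surv$event)
  res <- t(vapply(seq_len(nrow(M)), function(i) {
    w <- as.vector(scale(M[i, ]))
    cf <- survival::coxph(ss ~ w)
    sm <- summary(cf)
    c(LHR = unname(stats::coef(cf)[1]),
      se = sm$coefficients[1, "se(coef)"],
      p = unname(sm$sctest["pvalue"]))
  }, numeric(3)))
  out <- data.frame(component = rownames(M), res,
                    adj_p = benjamini_hochberg(res[, "p"]),
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("component_survival", "data.frame")
  out
}

#' Survival-weighted risk score model
#'
#' Builds the component risk score: for each sample j,
#' `RS_j = sum_i H_i * R2_i * M*_ij`, where `H_i` is the log-hazard ratio of
#' component i when its BH-adjusted log-rank p is below `alpha` and 0
#' otherwise, `R2_i` is the component stability, and `M*_ij` is the weight
#' standardised with the discovery-cohort mean and sd of that weight row.
#' The standardisation parameters are frozen at training time and reused
#' when scoring new cohorts, so discovery-derived components transfer
#' without leakage.
#'
#' @param fit a `consica` object (provides weights and stability).
#' @param surv survival data.frame as in [cox_per_component()].
#' @param alpha significance threshold on the adjusted p (default 0.05).
#' @param screen optionally, a precomputed result of [cox_per_component()].
#' @return object of class `risk_score_model`: data.frame-backed list with
#'   per-component H, stability, mu, sd, plus `alpha` and the screen table.
#' @export
build_risk_score <- function(fit, surv, alpha = 0.05, screen = NULL) {
  stopifnot(inherits(fit, "consica"))
  if (is.null(screen)) screen <- cox_per_component(fit, surv)
  H <- ifelse(screen$adj_p < alpha, screen$LHR, 0)
  mu <- rowMeans(fit$M)
  sdv <- apply(fit$M, 1, stats::sd)
  if (any(sdv[H != 0] <= 0)) stop("retained component has zero weight sd")
  structure(list(component = screen$component, H = H,
                 stability = unname(fit$stability[screen$component]),
                 mu = unname(mu[screen$component]),
                 sd = unname(sdv[screen$component]),
                 alpha = alpha, screen = screen),
            class = "risk_score_model")
}

#' @export
print.risk_score_model <- function(x, ...) {
  ns <- sum(x$H != 0)
  cat(sprintf("Risk score model: %d of %d components survival-significant (adj.p < %g)\n",
              ns, length(x$H), x$alpha))
  if (ns > 0) {
    sel <- x$H != 0
    print(data.frame(component = x$component[sel], LHR = x$H[sel],
                     stability = x$stability[sel]), row.names = FALSE,
          digits = 3)
  }
  invisible(x)
}

#' Score samples with a risk score model
#'
#' @param model a `risk_score_model`.
#' @param M_new k x m weight matrix for the samples to score; must contain
#'   a row for every model component (matched by name).
#' @return named numeric vector of risk scores.
#' @export
score_samples <- function(model, M_new) {
  miss <- setdiff(model$component, rownames(M_new))
  if (length(miss) > 0L)
    stop("weight matrix lacks component row(s): ", paste(miss, collapse = ", "))
  M_new <- M_new[model$component, , drop = FALSE]
  Mstar <- (M_new - model$mu) / model$sd
  rs <- as.vector(crossprod(Mstar, model$H * model$stability))
  stats::setNames(rs, colnames(M_new))
}

#' @param object a `risk_score_model`.
#' @param newdata weight matrix; defaults must be supplied explicitly.
#' @param ... unused.
#' @rdname score_samples
#' @export
predict.risk_score_model <- function(object, newdata, ...) {
  score_samples(object, newdata)
}

#' Classify samples from component weights
#'
#' Trains a random forest (default settings) on the columns of the weight
#' matrix and reports leave-one-out cross-validated accuracy, per-class
#' sensitivity and specificity, and the out-of-fold class vote fractions per
#' sample. Deterministic given `seed`.
#'
#' @param fit a `consica` object or k x m weight matrix.
#' @param labels factor (or coercible) of length m, >= 2 classes with >= 5
#'   samples each.
#' @param seed integer seed.
#' @return list of class `weight_classifier`: `model` (forest trained on
#'   all samples), `accuracy` (LOOCV), `per_class` (data.frame class,
#'   sensitivity, specificity), `votes` (m x classes matrix), `predicted`.
#' @export
classify_and_validate <- function(fit, labels, seed = 1L) {
  M <- if (inherits(fit, "consica")) fit$M else fit
  y <- factor(labels)
  if (nlevels(y) < 2L) stop("need at least 2 classes")
  if (any(table(y) < 5L)) stop("need >= 5 samples per class")
  X <- t(M)
  m <- nrow(X)
  set.seed(seed)
  votes <- matrix(NA_real_, m, nlevels(y),
                  dimnames = list(rownames(X), levels(y)))
  pred <- factor(rep(NA_character_, m), levels = levels(y))
  for (j in seq_len(m)) {
    rf <- randomForest::randomForest(X[-j, , drop = FALSE], y[-j])
    votes[j, ] <- stats::predict(rf, X[j, , drop = FALSE], type = "prob")
    pred[j] <- stats::predict(rf, X[j, , drop = FALSE])
  }
  acc <- mean(pred == y)
  per_class <- do.call(rbind, lapply(levels(y), function(cl) {
    tp <- sum(pred == cl & y == cl); fn <- sum(pred != cl & y == cl)
    tn <- sum(pred != cl & y != cl); fp <- sum(pred == cl & y != cl)
    data.frame(class = cl, sensitivity = tp / (tp + fn),
               specificity = tn / (tn + fp), stringsAsFactors = FALSE)
  }))
  final <- randomForest::randomForest(X, y)
  structure(list(model = final, accuracy = acc, per_class = per_class,
                 votes = votes, predicted = pred, seed = seed),
            class = "weight_classifier")
}

#' @export
print.weight_classifier <- function(x, ...) {
  cat(sprintf("Weight-based classifier: LOOCV accuracy %.3f\n", x$accuracy))
  print(x$per_class, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Choose the number of components by nested cross-validation
#'
#' Holds out 20% of the samples, decomposes the remaining 80% at each
#' candidate k, scores leave-one-out classification accuracy of the weights
#' on the inner set, and picks the smallest k whose accuracy is within one
#' standard error of the best (accuracy SE from the binomial formula at the
#' inner sample count).
#'
#' @param E expression matrix (features x samples).
#' @param labels class labels per sample.
#' @param candidate_ks increasing integer vector of candidate component
#'   counts; every k must be < 80% of the sample count.
#' @param nt runs per consensus decomposition during the search (small by
#'   design; the final model is refit at full nt).
#' @param seed integer seed (controls the outer split and all inner fits).
#' @return list: `k` (chosen), `profile` (data.frame k, accuracy, se),
#'   `holdout_ids`.
#' @export
select_num_components <- function(E, labels, candidate_ks, nt = 10L,
                                  seed = 1L) {
  X <- unclass(E)
  m <- ncol(X)
  if (is.unsorted(candidate_ks)) stop("candidate_ks must be sorted ascending")
  set.seed(seed)
  hold <- sample.int(m, ceiling(0.2 * m))
  inner <- setdiff(seq_len(m), hold)
  if (max(candidate_ks) >= length(inner))
    stop("candidate k >= inner sample count")
  y <- factor(labels)[inner]
  acc <- vapply(candidate_ks, function(k) {
    d <- consica(X[, inner, drop = FALSE], k = k, nt = nt,
                 seed = seed + k)
    classify_and_validate(d$M, y, seed = seed)$accuracy
  }, numeric(1))
  se <- sqrt(acc * (1 - acc) / length(inner))
  best <- which.max(acc)
  ok <- which(acc >= acc[best] - se[best])
  choice <- candidate_ks[min(ok)]
  list(k = choice,
       profile = data.frame(k = candidate_ks, accuracy = acc, se = se),
       holdout_ids = colnames(X)[hold])
}

#' Read a clinical TSV
#'
#' Expected columns: sample_id, time, event, plus arbitrary label columns.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_clinical <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
  if (!"sample_id" %in% names(df)) stop("clinical table needs a sample_id column")
  df
}

#' Split samples by the median risk score
#'
#' Convenience two-group report for Kaplan-Meier style display: samples at
#' or below the median score form the low-risk group.
#'
#' @param rs named numeric vector of risk scores.
#' @return factor with levels `low`/`high`.
#' @export
risk_groups <- function(rs) {
  cut <- stats::median(rs)
  factor(ifelse(rs > cut, "high", "low"), levels = c("low", "high"))
}
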