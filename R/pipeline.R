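#' Pipeline configuration
#'
#' Validates and bundles all parameters of an end-to-end run:
#' decomposition (k, nt, seed), significance thresholds (top contributors,
#' survival screen, link r^2), and optional annotation resources.
#'
#' @param k components for the mRNA-layer decomposition.
#' @param nt consensus runs.
#' @param seed master seed.
#' @param alpha_features adjusted-p threshold for top contributors
#'   (default 0.01).
#' @param alpha_survival adjusted-p threshold for the Cox screen
#'   (default 0.05).
#' @param r2_link strict r^2 threshold for component linking
#'   (default 0.25).
#' @param k_mirna optional components for a second (miRNA) layer.
#' @param gmt optional path to a GMT gene-set file.
#' @param out_dir output directory for persisted artifacts and the report.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(k, nt = 100L, seed = 1L, alpha_features = 0.01,
                            alpha_survival = 0.05, r2_link = 0.25,
                            k_mirna = NULL, gmt = NULL,
                            out_dir = tempfile("cicada_run_")) {
  for (a in list(alpha_features, alpha_survival, r2_link))
    if (!is.numeric(a) || length(a) != 1L || a <= 0 || a >= 1)
      stop("thresholds must lie strictly within (0, 1)")
  if (nt < 2L) stop("'nt' must be >= 2")
  if (k < 1L) stop("'k' must be >= 1")
  structure(list(k = as.integer(k), nt = as.integer(nt),
                 seed = as.integer(seed), alpha_features = alpha_features,
                 alpha_survival = alpha_survival, r2_link = r2_link,
                 k_mirna = if (!is.null(k_mirna)) as.integer(k_mirna),
                 gmt = gmt, out_dir = out_dir),
            class = "pipeline_config")
}

pipe_log <- function(stage, ...) {
  message(sprintf("[cicada] %s: %s", stage, sprintf(...)))
}

#' Run the full deconvolution pipeline
#'
#' Executes decompose -> annotate -> survival -> (link) -> project ->
#' report on one (or two) expression matrices, persisting every
#' intermediate artifact as TSV/JSON under `cfg$out_dir` and writing a
#' Markdown report with one section per component (stability, top
#' contributors, enrichment, survival statistics, linked components) and a
#' samples section (risk scores, ranking-score table for the new samples).
#' All outputs are a pure function of the inputs and `cfg$seed`; a re-run
#' with the same configuration reproduces them byte for byte. A stage
#' failure halts the pipeline with the stage named; artifacts persisted by
#' earlier stages are retained.
#'
#' @param E `expr_matrix`, features x samples (log-like scale).
#' @param cfg a `pipeline_config`.
#' @param surv optional survival data.frame (sample_id, time, event).
#' @param labels optional class labels for weight-based classification.
#' @param E_mirna optional second-layer matrix (requires `cfg$k_mirna`);
#'   linked to the first layer by weight correlation.
#' @param new_sample_ids optional character vector naming which columns of
#'   `E` are "new" samples to be projected as ranking scores (defaults to
#'   none).
#' @return list of class `pipeline_result` with the fitted objects and the
#'   path of the report.
#' @export
run_pipeline <- function(E, cfg, surv = NULL, labels = NULL, E_mirna = NULL,
                         new_sample_ids = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    pipe_log(name, "start (seed %d)", cfg$seed)
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  fit <- stage("decompose", {
    f <- consica(E, k = cfg$k, nt = cfg$nt, seed = cfg$seed)
    write_decomposition(f, file.path(cfg$out_dir, "decomposition"))
    f
  })

  fit <- stage("orient", orient_components(fit, alpha = cfg$alpha_features))
  sigs <- stage("annotate", {
    s <- component_signatures(fit, alpha = cfg$alpha_features)
    write_signatures(s, file.path(cfg$out_dir, "signatures.tsv"))
    s
  })

  enr <- NULL
  if (!is.null(cfg$gmt)) enr <- stage("enrich", {
    sets <- read_gmt(cfg$gmt)
    lapply(sigs, function(sg)
      enrich_signature(sg$positive$feature_id, sets, fit$feature_ids))
  })

  rs_model <- NULL; rs <- NULL
  if (!is.null(surv)) {
    rs_model <- stage("survival", {
      m <- build_risk_score(fit, surv, alpha = cfg$alpha_survival)
      jsonlite::write_json(
        list(component = m$component, H = m$H, stability = m$stability,
             mu = m$mu, sd = m$sd, alpha = m$alpha),
        file.path(cfg$out_dir, "risk_score_model.json"),
        auto_unbox = TRUE, digits = NA)
      m
    })
    rs <- score_samples(rs_model, fit$M)
    utils::write.table(
      data.frame(sample_id = names(rs), RS = unname(rs)),
      file.path(cfg$out_dir, "risk_scores.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }

  clf <- NULL
  if (!is.null(labels)) clf <- stage("classify", {
    classify_and_validate(fit, labels, seed = cfg$seed)
  })

  fit_mirna <- NULL; graph <- NULL
  if (!is.null(E_mirna)) {
    if (is.null(cfg$k_mirna)) stop("cfg$k_mirna required with E_mirna")
    fit_mirna <- stage("decompose_mirna", {
      f <- consica(E_mirna, k = cfg$k_mirna, nt = cfg$nt,
                   seed = cfg$seed + 1L)
      orient_mirna_by_link(f, fit)
    })
    graph <- stage("link", {
      g <- link_components(fit, fit_mirna, r2_threshold = cfg$r2_link,
                           layers = c("RIC", "MIC"))
      write_component_graph(g, file.path(cfg$out_dir, "links.tsv"))
      g
    })
  }

  ranks <- NULL
  if (!is.null(new_sample_ids)) ranks <- stage("project", {
    rp <- rank_profile(fit, M_new = fit$M[, new_sample_ids, drop = FALSE])
    utils::write.table(
      data.frame(sample_id = rownames(rp), unclass(rp), check.names = FALSE),
      file.path(cfg$out_dir, "ranking_scores.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    rp
  })

  report <- stage("report", {
    path <- file.path(cfg$out_dir, "report.md")
    write_report(path, cfg, fit, sigs, enr, rs_model, rs, clf, graph, ranks)
    path
  })

  structure(list(fit = fit, signatures = sigs, enrichment = enr,
                 risk_model = rs_model, risk_scores = rs, classifier = clf,
                 fit_mirna = fit_mirna, graph = graph, ranks = ranks,
                 report = report, config = cfg),
            class = "pipeline_result")
}

fmt_num <- function(x, digits = 6) formatC(x, digits = digits, format = "g")

write_report <- function(path, cfg, fit, sigs, enr, rs_model, rs, clf,
                         graph, ranks) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("# Consensus ICA deconvolution report")
  w("")
  w("Parameters: k = %d, nt = %d, seed = %d; thresholds: top contributors adj.p < %g, survival adj.p < %g, link r^2 > %g",
    cfg$k, cfg$nt, cfg$seed, cfg$alpha_features, cfg$alpha_survival,
    cfg$r2_link)
  w("")
  for (i in seq_len(fit$k)) {
    cid <- colnames(fit$S)[i]
    w("## Component %s", cid)
    w("")
    w("- stability R^2: %s", fmt_num(fit$stability[i]))
    sg <- sigs[[cid]]
    w("- top contributors: %d positive, %d negative (adj.p < %g)",
      nrow(sg$positive), nrow(sg$negative), sg$alpha)
    if (nrow(sg$positive))
      w("- leading positive features: %s",
        paste(utils::head(sg$positive$feature_id, 5), collapse = ", "))
    if (!is.null(enr) && nrow(enr[[cid]]) > 0) {
      top <- enr[[cid]][1, ]
      w("- best enriched set: %s (adj.p = %s)", top$set, fmt_num(top$adj_p))
    }
    if (!is.null(rs_model)) {
      row <- rs_model$screen[rs_model$screen$component == cid, ]
      w("- survival: LHR = %s, log-rank adj.p = %s%s",
        fmt_num(row$LHR), fmt_num(row$adj_p),
        if (rs_model$H[rs_model$component == cid] != 0)
          " (in risk score)" else "")
    }
    if (!is.null(graph)) {
      ed <- graph$edges
      hit <- ed[ed$node_a == paste0("RIC:", cid) |
                ed$node_b == paste0("RIC:", cid), , drop = FALSE]
      if (nrow(hit))
        w("- linked components: %s",
          paste(sprintf("%s (r=%s)",
                        ifelse(hit$node_a == paste0("RIC:", cid),
                               hit$node_b, hit$node_a),
                        fmt_num(hit$r, 3)), collapse = ", "))
    }
    w("")
  }
  w("## Samples")
  w("")
  if (!is.null(rs)) {
    w("Risk scores (RS):")
    w("")
    w("sample_id\tRS")
    for (j in seq_along(rs)) w("%s\t%s", names(rs)[j], fmt_num(rs[j]))
    w("")
  }
  if (!is.null(clf)) {
    w("Weight-based classification: LOOCV accuracy = %s", fmt_num(clf$accuracy))
    w("")
  }
  if (!is.null(ranks)) {
    w("Ranking scores of new samples (0-1, relative to discovery):")
    w("")
    w("sample_id\t%s", paste(colnames(ranks), collapse = "\t"))
    for (j in seq_len(nrow(ranks)))
      w("%s\t%s", rownames(ranks)[j],
        paste(fmt_num(ranks[j, ], 4), collapse = "\t"))
    w("")
  }
  invisible(path)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Pipeline result\n")
  print(x$fit)
  cat("Report:", x$report, "\n")
  invisible(x)
}
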