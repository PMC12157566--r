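.config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

# FC vectors per run restricted to a block of a combined analysis
.block_fc_vectors <- function(fcs, block, part) {
  idx <- switch(block,
                all = NULL,
                brain = part$brain,
                spine = part$spine,
                stop("unknown block: ", block))
  lapply(1:2, function(r) {
    do.call(cbind, lapply(fcs, function(subj) {
      m <- subj[[r]]
      if (is.null(idx)) .vec_upper(m)
      else .vec_upper(m[idx, idx, drop = FALSE])
    }))
  })
}

.interaction_vectors <- function(fcs, part) {
  lapply(1:2, function(r) {
    do.call(cbind, lapply(fcs, function(subj) {
      as.vector(t(subj[[r]][part$brain, part$spine, drop = FALSE]))
    }))
  })
}

.block_metrics <- function(run1, run2, top_k, pca_sweep) {
  fp <- fingerprint_analysis(run1, run2, top_k = top_k)
  out <- list(
    Iself = fp$Iself, Iothers = fp$Iothers, Idiff = fp$Idiff,
    cohens_d = fp$cohens_d,
    accuracy_topk = as.list(fp$accuracy_topk),
    chance_level = round(fp$chance_level, 1),
    n_identified = length(fp$identified))
  if (pca_sweep) {
    sweep <- pca_differential_identifiability(run1, run2)
    out$m_star <- sweep$m_star
    out$idiff_star <- sweep$idiff_star
    attr(out, "pca_sweep") <- sweep
  }
  attr(out, "I") <- fp$I
  out
}

#' End-to-end fingerprinting analysis
#'
#' Chains the pipeline stages -- (optional) simulation or manifest loading,
#' FC construction, block extraction, fingerprinting with the optional
#' PCA sweep, edge-wise ICC with percentile thresholding and nodal
#' strength, and (for paired brain+spine data) cross-regression residual
#' fingerprints -- into a single reproducible report.
#'
#' @param config a list with elements:
#'   \describe{
#'     \item{simulate}{list describing a simulation: either
#'       `list(kind = "cohort", ...)` with [cohort_spec()] arguments, or
#'       `list(kind = "driven_pair", n_target =, mixing_density =,
#'       target_noise_sd =, ...)`; mutually exclusive with `manifest`.}
#'     \item{manifest}{path to a two-run manifest TSV (see
#'       [read_manifest()]).}
#'     \item{scheme}{optional path to a scheme TSV, or a
#'       `parcellation_scheme`.}
#'     \item{blocks}{character subset of `c("all", "brain", "spine",
#'       "interaction")`; blocks other than `"all"` need a combined
#'       scheme or a driven pair. Default `"all"`.}
#'     \item{top_k}{K values for accuracy curves, default `1:5`.}
#'     \item{pca_sweep}{logical, run the differential-identifiability
#'       sweep per block (default `FALSE`).}
#'     \item{icc}{logical, compute the edge ICC map (default `TRUE`).}
#'     \item{icc_quantile}{threshold quantile, default `0.95`.}
#'     \item{nodal_mode}{`"sum"` (default) or `"mean"`.}
#'     \item{cross_regression}{logical; residual fingerprints in both
#'       directions (needs brain+spine blocks), default `FALSE`.}
#'     \item{seed}{integer seed for simulation, default 1.}
#'   }
#' @param out_dir optional directory; when given, identifiability
#'   matrices, ICC maps, Idiff-vs-m curves and the JSON report are
#'   written there.
#' @return An `analysis_report` list: `provenance` (seed, config hash,
#'   package version), `blocks` (per-block metrics), `icc` (threshold,
#'   max, nodal strengths) and optionally `cross_regression`.
#' @export
run_full_analysis <- function(config, out_dir = NULL) {
  blocks <- config$blocks %||% "all"
  top_k <- config$top_k %||% 1:5
  pca_sweep <- isTRUE(config$pca_sweep)
  do_icc <- config$icc %||% TRUE
  icc_q <- config$icc_quantile %||% 0.95
  nodal_mode <- config$nodal_mode %||% "sum"
  seed <- config$seed %||% 1L

  if (!is.null(out_dir))
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  scheme <- config$scheme
  if (is.character(scheme)) scheme <- read_scheme(scheme)

  part <- NULL
  if (!is.null(config$simulate)) {
    sim <- config$simulate
    kind <- sim$kind %||% "cohort"
    spec_args <- sim[setdiff(names(sim),
                             c("kind", "n_target", "mixing_density",
                               "target_noise_sd"))]
    spec_args$seed <- seed
    spec <- do.call(cohort_spec, spec_args)
    if (kind == "driven_pair") {
      pair <- generate_driven_pair(
        spec, n_target = sim$n_target,
        mixing_density = sim$mixing_density %||% 0.3,
        target_noise_sd = sim$target_noise_sd %||% 0.5)
      series <- lapply(seq_len(spec$n_subjects), function(i) {
        lapply(1:2, function(r) {
          run_timeseries(rbind(unclass(pair$x[[i]][[r]]),
                               unclass(pair$y[[i]][[r]])),
                         TR = spec$TR,
                         subject_id = sprintf("sub-%02d", i),
                         run_id = sprintf("run-%d", r))
        })
      })
      nx <- spec$n_regions
      part <- list(brain = seq_len(nx),
                   spine = nx + seq_len(sim$n_target))
    } else {
      series <- generate_cohort(spec, scheme = scheme)$series
    }
  } else if (!is.null(config$manifest)) {
    series <- load_manifest_runs(config$manifest, scheme = scheme)
  } else {
    stop("config must provide either `simulate` or `manifest`")
  }
  if (is.null(part) && !is.null(scheme) && scheme$kind == "combined")
    part <- scheme_partition(scheme)
  if (is.null(part) && any(blocks != "all"))
    stop("blocks other than 'all' need a combined scheme or a driven pair")

  fcs <- lapply(series, function(subj) lapply(subj, compute_fc))

  report <- list(
    provenance = list(
      seed = seed,
      config_hash = .config_hash(config),
      package = as.character(utils::packageVersion("spineprint")),
      n_subjects = length(series),
      n_regions = nrow(series[[1]][[1]]),
      n_timepoints = ncol(series[[1]][[1]])),
    blocks = list())

  matrices <- list()
  for (b in blocks) {
    vecs <- if (b == "interaction") .interaction_vectors(fcs, part)
            else .block_fc_vectors(fcs, b, part)
    metrics <- .block_metrics(vecs[[1]], vecs[[2]], top_k, pca_sweep)
    matrices[[b]] <- attr(metrics, "I")
    sweep <- attr(metrics, "pca_sweep")
    attributes(metrics) <- list(names = names(metrics))
    report$blocks[[b]] <- metrics
    if (!is.null(out_dir) && !is.null(sweep)) {
      utils::write.table(
        data.frame(m = as.integer(names(sweep$idiff_by_components)),
                   idiff = .fmt(sweep$idiff_by_components)),
        file.path(out_dir, sprintf("idiff_vs_m_%s.tsv", b)),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  if (do_icc) {
    vecs <- .block_fc_vectors(fcs, "all", part)
    map <- edge_icc(vecs[[1]], vecs[[2]], scheme = scheme)
    thr <- threshold_percentile(map, icc_q)
    strengths <- nodal_strength(thr$filtered, mode = nodal_mode)
    report$icc <- list(
      quantile = icc_q, threshold = thr$threshold,
      max = max(map[upper.tri(map)], na.rm = TRUE),
      nodal_mode = nodal_mode,
      nodal_strength = as.list(stats::setNames(as.numeric(strengths),
                                               names(strengths))))
    if (!is.null(out_dir)) {
      write_matrix(map, file.path(out_dir, "icc_map.tsv"))
      write_matrix(thr$filtered, file.path(out_dir, "icc_filtered.tsv"))
    }
  }

  if (isTRUE(config$cross_regression)) {
    if (is.null(part))
      stop("cross_regression needs a combined scheme or a driven pair")
    fit_dir <- function(target_idx, pred_idx, label) {
      fits <- lapply(1:2, function(r) {
        lapply(series, function(subj) {
          m <- unclass(subj[[r]])
          fit_cross_regression(m[target_idx, , drop = FALSE],
                               m[pred_idx, , drop = FALSE],
                               direction = label)
        })
      })
      fp <- residual_fingerprint(fits[[1]], fits[[2]], top_k = top_k)
      list(Idiff = fp$Idiff, cohens_d = fp$cohens_d,
           accuracy_topk = as.list(fp$accuracy_topk),
           n_identified = length(fp$identified),
           mean_r_squared = mean(vapply(fits[[1]],
                                        function(f) mean(f$r_squared),
                                        numeric(1))))
    }
    report$cross_regression <- list(
      brain_to_spine = fit_dir(part$spine, part$brain, "brain_to_spine"),
      spine_to_brain = fit_dir(part$brain, part$spine, "spine_to_brain"))
  }

  class(report) <- "analysis_report"
  if (!is.null(out_dir)) {
    for (b in names(matrices)) {
      I <- matrices[[b]]
      dimnames(I) <- list(sprintf("sub%02d_run1", seq_len(nrow(I))),
                          sprintf("sub%02d_run2", seq_len(ncol(I))))
      write_matrix(I, file.path(out_dir, sprintf("identifiability_%s.tsv", b)))
    }
    write_report(report, file.path(out_dir, "report.json"))
  }
  report
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("analysis_report\n")
  for (b in names(x$blocks)) {
    m <- x$blocks[[b]]
    cat(sprintf(
      "  [%s] Idiff = %.3f, d = %.2f, K=1 accuracy = %.1f%% (chance %.1f%%)\n",
      b, m$Idiff, m$cohens_d, m$accuracy_topk[["1"]], m$chance_level))
  }
  if (!is.null(x$icc))
    cat(sprintf("  ICC: threshold(q=%.2f) = %.3f, max = %.3f\n",
                x$icc$quantile, x$icc$threshold, x$icc$max))
  if (!is.null(x$cross_regression))
    cat(sprintf(
      "  residual fingerprints: spine|brain Idiff = %.3f, brain|spine Idiff = %.3f\n",
      x$cross_regression$brain_to_spine$Idiff,
      x$cross_regression$spine_to_brain$Idiff))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
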