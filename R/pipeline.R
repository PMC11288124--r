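#' Extract the three feature blocks for a cohort
#'
#' Runs the copy-number, fragment-size-distribution and nucleosome-
#' footprint extractors over a list of samples, against a shared bin grid,
#' arm set, site-set collection and healthy-panel baseline, and returns
#' aligned samples x features matrices.
#'
#' @param samples list of `sample_fragments`.
#' @param bins a `bin_grid` with `gc`.
#' @param arms an `arm_set`.
#' @param site_sets named list of site sets.
#' @param baseline a [cnv_baseline()] (built from the healthy panel).
#' @param fsd_edges size-bin edges (default [fsd_bin_edges()]).
#' @param gc_model optional fragment-GC weight function for NF.
#' @param nf_window,nf_step composite-profile window config.
#' @return named list of matrices `CNV`, `FSD`, `NF` with sample ids as
#'   rownames.
#' @export
cohort_features <- function(samples, bins, arms, site_sets, baseline,
                            fsd_edges = fsd_bin_edges(), gc_model = NULL,
                            nf_window = 960, nf_step = 15) {
  ids <- vapply(samples, `[[`, "", "sample_id")
  cnv <- t(vapply(samples, function(s) {
    d <- gc_correct(bin_depths(s, bins), bins$gc, bins$kept)
    cnv_features(log2_ratios(d, baseline, bins$kept), bins)
  }, numeric(sum(bins$kept))))
  fsd <- t(vapply(samples, function(s) fsd_features(s, arms, fsd_edges),
                  numeric(nrow(arms) * (length(fsd_edges) - 1))))
  nf <- t(vapply(samples, function(s)
    nf_features(s, site_sets, gc_model, nf_window, nf_step),
    numeric(3L * length(site_sets))))
  rownames(cnv) <- rownames(fsd) <- rownames(nf) <- ids
  list(CNV = cnv, FSD = fsd, NF = nf)
}

#' Evaluate scored cohort predictions
#'
#' AUC with a bootstrap percentile CI, sensitivity/specificity at the given
#' calls with Wilson intervals, and (optionally) per-stage sensitivity.
#'
#' @param scores numeric cancer scores.
#' @param labels true labels.
#' @param calls logical calls (score >= threshold).
#' @param stage optional per-sample stage (cancer samples).
#' @param B bootstrap replicates (default 1000).
#' @param conf confidence level.
#' @param ci_method "wilson" or "exact".
#' @param seed bootstrap seed.
#' @return list of class `cohort_eval`.
#' @export
evaluate_cohort <- function(scores, labels, calls, stage = NULL, B = 1000,
                            conf = 0.95, ci_method = "wilson", seed = 1L) {
  y <- as_binary_labels(labels)
  ss <- sens_spec(calls, y, ci = ci_method, conf = conf)
  out <- list(scores = scores, labels = y, calls = as.logical(calls),
              auc = roc_auc(scores, y),
              auc_ci = bootstrap_auc_ci(scores, y, B = B, conf = conf, seed = seed),
              sensitivity = ss$sensitivity, specificity = ss$specificity)
  if (!is.null(stage)) {
    tab <- lapply(split(seq_along(y)[y == 1 & !is.na(stage)],
                        stage[y == 1 & !is.na(stage)]), function(ii)
      c(n = length(ii), detected = sum(calls[ii]),
        sensitivity = mean(calls[ii])))
    out$by_stage <- do.call(rbind, tab)
  }
  structure(out, class = "cohort_eval")
}

#' @exportS3Method base::print
print.cohort_eval <- function(x, ...) {
  cat(sprintf("<cohort_eval> AUC %.3f (%.3f-%.3f); sens %.3f; spec %.3f\n",
              x$auc, x$auc_ci[1], x$auc_ci[2],
              x$sensitivity$estimate, x$specificity$estimate))
  invisible(x)
}

#' Default end-to-end run configuration
#'
#' All pipeline constants (down-sampling target, bin width, size-bin edges,
#' NF window, fold count, ensemble size, specificity target, bootstrap
#' replicates) live here as editable config, never as literals inside the
#' stages.
#'
#' @return nested configuration list.
#' @export
default_run_config <- function() {
  list(
    seed = 1L,
    out_dir = NULL,
    cohort = list(n_train_cancer = 20L, n_train_healthy = 20L,
                  n_test_cancer = 10L, n_test_healthy = 10L,
                  depth = 5, f_min = 0.05, f_max = 0.30),
    sim = list(n_site_sets = 10L, sites_per_set = 200L),
    features = list(bin_width = 1e6, fsd_edges = fsd_bin_edges(),
                    nf_window = 960, nf_step = 15),
    model = list(k = 5L, top_k = 5L, target_specificity = 0.95),
    eval = list(bootstrap_B = 1000L, conf = 0.95))
}

#' Run the full synthetic-cohort pipeline
#'
#' simulate -> extract features -> train the stacked ensemble -> score the
#' held-out cohort -> evaluate. With an `out_dir`, feature matrices (TSV),
#' the evaluation (JSON) and a manifest carrying the master seed and a
#' config hash are written; reruns with the same seed produce byte-
#' identical feature files.
#'
#' @param config a config list as from [default_run_config()] (partial
#'   lists are filled with defaults) or a path to a YAML file with the same
#'   structure.
#' @param grids hyperparameter grids (default [default_grids()]).
#' @return list: `model`, `train_blocks`, `test_blocks`, `labels`,
#'   `eval` (a `cohort_eval` on the held-out cohort), `config`.
#' @export
run_pipeline <- function(config = list(), grids = default_grids()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  cfg <- utils::modifyList(default_run_config(), config)
  if (!is.null(cfg$out_dir) && !dir.exists(dirname(cfg$out_dir)))
    stop("output parent directory does not exist: ", dirname(cfg$out_dir))

  set.seed(cfg$seed)
  stage_seeds <- sample.int(2147483646L, 6)
  layout <- miniature_layout()
  profile <- miniature_profile()
  sites <- miniature_sites(layout, cfg$sim$n_site_sets, cfg$sim$sites_per_set,
                           seed = stage_seeds[1])
  bins <- sim_bin_gc(make_bins(layout, cfg$features$bin_width), profile, layout)
  arms <- list_arms(layout, drop_acrocentric_p = FALSE)

  f_dist <- function(n) stats::runif(n, cfg$cohort$f_min, cfg$cohort$f_max)
  train_plan <- .cohort_plan(cfg$cohort$n_train_cancer, cfg$cohort$n_train_healthy,
                             f_dist, stage_seeds[2])
  test_plan <- .cohort_plan(cfg$cohort$n_test_cancer, cfg$cohort$n_test_healthy,
                            f_dist, stage_seeds[3])

  # samples are simulated one at a time and reduced to their feature rows
  # immediately, so a full-depth cohort never sits in memory at once
  scan <- function(plan) {
    depths <- matrix(0, nrow(bins), nrow(plan))
    fsd <- nf <- NULL
    for (i in seq_len(nrow(plan))) {
      s <- simulate_sample(profile, layout, plan$f[i], cfg$cohort$depth,
                           plan$seed[i], sites, sample_id = plan$id[i])
      depths[, i] <- bin_depths(s, bins)
      frow <- fsd_features(s, arms, cfg$features$fsd_edges)
      nrow_ <- nf_features(s, sites, NULL, cfg$features$nf_window,
                           cfg$features$nf_step)
      if (is.null(fsd)) {
        fsd <- matrix(0, nrow(plan), length(frow),
                      dimnames = list(plan$id, names(frow)))
        nf <- matrix(0, nrow(plan), length(nrow_),
                     dimnames = list(plan$id, names(nrow_)))
      }
      fsd[i, ] <- frow
      nf[i, ] <- nrow_
    }
    list(depths = depths, fsd = fsd, nf = nf)
  }
  train_feat <- scan(train_plan)
  test_feat <- scan(test_plan)

  corr <- function(d) gc_correct(d, bins$gc, bins$kept)
  healthy_cols <- which(train_plan$label == "healthy")
  panel <- vapply(healthy_cols, function(i) corr(train_feat$depths[, i]),
                  numeric(nrow(bins)))
  expected <- apply(panel, 1, stats::median)
  expected[!bins$kept] <- NA_real_
  baseline <- list(expected = expected, gc = bins$gc,
                   n_panel = length(healthy_cols))

  cnv_block <- function(feat, plan) {
    m <- t(vapply(seq_len(nrow(plan)), function(i)
      cnv_features(log2_ratios(corr(feat$depths[, i]), baseline, bins$kept),
                   bins), numeric(sum(bins$kept))))
    rownames(m) <- plan$id
    m
  }
  train_blocks <- list(CNV = cnv_block(train_feat, train_plan),
                       FSD = train_feat$fsd, NF = train_feat$nf)
  test_blocks <- list(CNV = cnv_block(test_feat, test_plan),
                      FSD = test_feat$fsd, NF = test_feat$nf)

  model <- train_stacked(train_blocks, train_plan$label, k = cfg$model$k,
                         grids = grids, top_k = cfg$model$top_k,
                         target_specificity = cfg$model$target_specificity,
                         seed = stage_seeds[4])
  pred <- predict(model, test_blocks)
  ev <- evaluate_cohort(pred$score, test_plan$label, pred$call, test_plan$stage,
                        B = cfg$eval$bootstrap_B, conf = cfg$eval$conf,
                        seed = stage_seeds[5])

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    for (b in names(train_blocks)) {
      utils::write.table(train_blocks[[b]],
                         file.path(cfg$out_dir, paste0("train_", b, ".tsv")),
                         sep = "\t", quote = FALSE, col.names = NA)
      utils::write.table(test_blocks[[b]],
                         file.path(cfg$out_dir, paste0("test_", b, ".tsv")),
                         sep = "\t", quote = FALSE, col.names = NA)
    }
    cfg_path <- file.path(cfg$out_dir, "config.yaml")
    yaml::write_yaml(cfg, cfg_path)
    manifest <- list(seed = cfg$seed,
                     config_md5 = unname(tools::md5sum(cfg_path)),
                     threshold = model$threshold,
                     auc = ev$auc)
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(
      list(auc = ev$auc, auc_ci = as.list(ev$auc_ci),
           sensitivity = ev$sensitivity$estimate,
           specificity = ev$specificity$estimate),
      file.path(cfg$out_dir, "eval.json"), auto_unbox = TRUE, digits = NA)
  }

  list(model = model, train_blocks = train_blocks, test_blocks = test_blocks,
       labels = list(train = train_plan$label, test = test_plan$label),
       truth_f = list(train = train_plan$f, test = test_plan$f),
       eval = ev, pred = pred, config = cfg,
       assets = list(layout = layout, profile = profile, sites = sites,
                     bins = bins, arms = arms, baseline = baseline))
}
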