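#' Default pipeline configuration
#'
#' Parameters for an end-to-end run on synthetic data. Values are sized
#' for a compact demonstration run; every stage parameter mirrors the
#' corresponding module argument and can be overridden by supplying a
#' modified copy to [run_pipeline()]. The QC thresholds default to
#' ranges matched to the synthetic library sizes rather than the
#' deep-sequencing cutoffs of real 10x data ([qc_thresholds()] holds
#' those defaults).
#'
#' @param seed global seed; every stochastic stage derives its stream
#'   from it.
#' @param out_dir artifact directory.
#' @return nested list of class `run_config`.
#' @export
default_run_config <- function(seed = 1L, out_dir = tempfile("trajnoise_run")) {
  structure(list(
    seed = as.integer(seed),
    out_dir = out_dir,
    sim = list(n_genes = 300, n_cells_per_timepoint = 100,
               effect_size = 2, dispersion_low = 0.1, dispersion_high = 1),
    qc = list(min_reads = 50, max_reads = 1e7,
              min_genes = 5, max_genes = 1e6, max_mito_pct = 7),
    min_gene_mean = 0.01,
    normalize_scale = 1e4,
    trajectory = list(alpha = 0.05, correction = "bonferroni"),
    noise = list(n_mean_bins = 10, tail_frac = 0.2,
                 backtransform = "difference"),
    landscape = list(
      feature_names = c("SIN3A", "H3K27ac", "POL2", "ER", "FOXA1", "MAX"),
      informative_features = c("SIN3A", "H3K27ac", "ER"),
      assoc_strength = 2),
    rank = list(max_iter = 100, alpha = 0.05, n_trees = 200),
    tree = list(min_leaf = 50, complexity = 0.007),
    coexpr = list(n_pairs = 50, latent_rho = 0.5, n_cells = 500),
    timing = list(targeted_half_max_h = 5.5, control_half_max_h = 4,
                  noise_sd = 0.05, replicates = 3, span = 0.75,
                  grid_step = 0.1, direction = "slower")
  ), class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Values present in the file override the defaults of
#' [default_run_config()]; everything else keeps its default.
#'
#' @param path YAML file.
#' @return `run_config` list.
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_run_config(seed = user$seed %||% 1L,
                            out_dir = user$out_dir %||%
                              tempfile("trajnoise_run"))
  merge_cfg <- function(base, over) {
    for (nm in names(over)) {
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(over[[nm]])) {
        merge_cfg(base[[nm]], over[[nm]])
      } else {
        over[[nm]]
      }
    }
    base
  }
  merge_cfg(cfg, user)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

pipeline_stages <- c("simulate", "preprocess", "trajectory", "noise",
                     "regulatory", "rank", "coexpr", "timing")

wt_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  nrow(d)
}

#' Run the analysis pipeline end to end
#'
#' Executes the stages simulate, preprocess, trajectory, noise,
#' regulatory, rank, coexpr and timing in dependency order, writing
#' TSV artifacts for every stage and a JSON run manifest (parameters,
#' seed, package version, per-stage status and row counts) into
#' `config$out_dir`. Reruns with an identical config produce
#' byte-identical artifacts. A failing stage aborts the run with an
#' error naming the stage; the manifest records the failure and the
#' artifacts of completed stages are retained.
#'
#' @param config a [default_run_config()]-shaped list (or path to a
#'   YAML file understood by [read_run_config()]).
#' @param stages subset of stages to run (default all). Later stages
#'   require the artifacts of earlier ones in `out_dir`.
#' @return the manifest list, invisibly.
#' @export
run_pipeline <- function(config = default_run_config(),
                         stages = pipeline_stages) {
  if (is.character(config)) config <- read_run_config(config)
  stages <- match.arg(stages, pipeline_stages, several.ok = TRUE)
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed

  manifest <- list(seed = seed,
                   package_version = as.character(utils::packageVersion("trajnoise")),
                   parameters = config[setdiff(names(config), "out_dir")],
                   stages = list())
  state <- new.env(parent = emptyenv())

  need_file <- function(stage, path) {
    if (!file.exists(path)) {
      stopf("stage '%s': missing input %s (run its upstream stage first)",
            stage, basename(path))
    }
    path
  }

  run_stage <- function(name, fun) {
    rows <- tryCatch(fun(), error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(e))
      write_manifest(manifest, out)
      stopf("stage '%s' failed: %s", name, conditionMessage(e))
    })
    manifest$stages[[name]] <<- list(status = "completed", rows = rows)
  }

  # recompute in-memory state from disk artifacts so any later stage can
  # be run standalone against an existing out_dir
  ensure_norm <- function(stage) {
    if (!is.null(state$norm)) return(invisible())
    need_file(stage, file.path(out, "counts", "matrix.mtx"))
    cc <- read_counts_mtx(file.path(out, "counts"))
    cc <- filter_cells(cc, do.call(qc_thresholds, config$qc))
    norm <- log_normalize(cc, scale = config$normalize_scale)
    state$norm <- filter_genes(norm, min_mean = config$min_gene_mean)
    state$time_h <- cc$cell_meta$time_h
    stats0 <- gene_stats(state$norm,
                         ifelse(state$time_h == 0, "0h", "treated"))
    state$stats0 <- stats0[stats0$group == "0h", ]
    invisible()
  }
  ensure_calls <- function(stage) {
    if (!is.null(state$calls)) return(invisible())
    f <- need_file(stage, file.path(out, "trajectory_calls.tsv"))
    state$calls <- utils::read.table(f, sep = "\t", header = TRUE,
                                     stringsAsFactors = FALSE)
    invisible()
  }

  stage_funs <- list(
    simulate = function() {
      sc <- do.call(sim_config, c(config$sim, list(seed = seed)))
      sim <- simulate_counts(sc)
      write_counts_mtx(sim$counts, file.path(out, "counts"))
      land <- do.call(simulate_regulatory_landscape,
                      c(list(truth = sim$truth), config$landscape,
                        list(seed = seed)))
      write_landscape(land, file.path(out, "landscape"))
      co <- do.call(simulate_coexpressed_pairs,
                    c(config$coexpr, list(seed = seed)))
      write_counts_mtx(co$counts, file.path(out, "coexpr_counts"))
      wt_tsv(co$pairs, file.path(out, "coexpr_pairs.tsv"))
      wt_tsv(co$loops, file.path(out, "coexpr_loops.tsv"))
      tm <- config$timing
      tc <- rbind(
        simulate_perturbation_timecourse(
          tm$targeted_half_max_h, noise_sd = tm$noise_sd,
          replicates = tm$replicates, condition = "targeted", seed = seed),
        simulate_perturbation_timecourse(
          tm$control_half_max_h, noise_sd = tm$noise_sd,
          replicates = tm$replicates, condition = "control",
          seed = seed + 1L))
      wt_tsv(tc, file.path(out, "timecourse.tsv"))
      nrow(sim$truth)
    },
    preprocess = function() {
      ensure_norm("preprocess")
      wt_tsv(state$stats0, file.path(out, "gene_stats_0h.tsv"))
    },
    trajectory = function() {
      ensure_norm("trajectory")
      calls <- classify_trajectories(state$norm, state$time_h,
                                     alpha = config$trajectory$alpha,
                                     correction = config$trajectory$correction)
      state$calls <- calls
      means <- stats::setNames(state$stats0$mean, state$stats0$gene)
      state$mean_classes <- classify_mean_levels(means)
      n_reg <- sum(calls$label != "NotRegulated")
      controls <- if (n_reg >= 1) {
        sample_control_genes(calls, means, n_controls = min(n_reg, 50),
                             seed = seed)
      } else {
        character(0)
      }
      state$controls <- controls
      wt_tsv(state$mean_classes, file.path(out, "mean_classes.tsv"))
      wt_tsv(data.frame(gene = controls), file.path(out, "control_genes.tsv"))
      wt_tsv(as.data.frame(calls), file.path(out, "trajectory_calls.tsv"))
    },
    noise = function() {
      ensure_norm("noise")
      nz <- noise_table(state$stats0,
                        n_mean_bins = config$noise$n_mean_bins,
                        tail_frac = config$noise$tail_frac,
                        backtransform = config$noise$backtransform)
      state$noise <- nz
      wt_tsv(nz, file.path(out, "noise_table.tsv"))
    },
    regulatory = function() {
      ld <- file.path(out, "landscape")
      need_file("regulatory", file.path(ld, "loops.tsv"))
      rd <- function(f, ...) utils::read.table(file.path(ld, f), sep = "\t",
                                               header = TRUE,
                                               stringsAsFactors = FALSE, ...)
      tss <- rd("tss.tsv")
      ps <- rd("promoter_signal.tsv", check.names = FALSE)
      prom_sig <- as.matrix(ps[, -1, drop = FALSE])
      rownames(prom_sig) <- ps$gene
      enh <- utils::read.table(file.path(ld, "enhancers.bed"), sep = "\t",
                               col.names = c("chrom", "start", "end",
                                             "peak_id", "gene"),
                               stringsAsFactors = FALSE)
      es <- rd("enhancer_signal.tsv", check.names = FALSE)
      enh_sig <- as.matrix(es[, -1, drop = FALSE])
      rownames(enh_sig) <- es$peak_id
      loops <- rd("loops.tsv")
      er <- utils::read.table(file.path(ld, "er_peaks.bed"), sep = "\t",
                              col.names = c("chrom", "start", "end"),
                              stringsAsFactors = FALSE)
      prof <- build_regulatory_profiles(tss, prom_sig, enh, enh_sig,
                                        loops, er)
      state$profiles <- prof
      wt_tsv(data.frame(gene = rownames(prof$features), prof$features,
                        check.names = FALSE),
             file.path(out, "regulatory_features.tsv"))
    },
    rank = function() {
      if (is.null(state$profiles)) {
        need_file("rank", file.path(out, "landscape", "loops.tsv"))
        stage_funs$regulatory()
      }
      ensure_calls("rank")
      feats <- state$profiles$features
      y <- state$calls$label[match(rownames(feats), state$calls$gene)]
      keep <- !is.na(y)
      rk <- boruta_rank(feats[keep, , drop = FALSE], y[keep],
                        max_iter = config$rank$max_iter,
                        alpha = config$rank$alpha,
                        n_trees = config$rank$n_trees, seed = seed)
      state$ranking <- rk
      tree <- fit_decision_tree(feats[keep, , drop = FALSE], y[keep],
                                min_leaf = config$tree$min_leaf,
                                complexity = config$tree$complexity)
      writeLines(utils::capture.output(print(tree)),
                 file.path(out, "decision_tree.txt"))
      wt_tsv(as.data.frame(rk), file.path(out, "feature_decisions.tsv"))
    },
    coexpr = function() {
      need_file("coexpr", file.path(out, "coexpr_counts", "matrix.mtx"))
      cc <- read_counts_mtx(file.path(out, "coexpr_counts"))
      pairs <- utils::read.table(file.path(out, "coexpr_pairs.tsv"),
                                 sep = "\t", header = TRUE,
                                 stringsAsFactors = FALSE)
      norm <- log_normalize(cc)
      obs <- pairwise_spearman(norm, pairs)
      ctl <- pairwise_spearman(norm, shuffle_pairs(pairs, seed = seed))
      cmp <- compare_pair_sets(obs$rho, ctl$rho)
      obs$provenance <- "planted"
      res <- rbind(obs[, c("gene_a", "gene_b", "provenance", "rho")],
                   ctl[, c("gene_a", "gene_b", "provenance", "rho")])
      state$coexpr_cmp <- cmp
      wt_tsv(data.frame(statistic = cmp$statistic, p_value = cmp$p_value,
                        p_adjusted = cmp$p_adjusted),
             file.path(out, "coexpr_comparison.tsv"))
      wt_tsv(res, file.path(out, "coexpr_rho.tsv"))
    },
    timing = function() {
      need_file("timing", file.path(out, "timecourse.tsv"))
      tc <- utils::read.table(file.path(out, "timecourse.tsv"), sep = "\t",
                              header = TRUE, stringsAsFactors = FALSE)
      tm <- config$timing
      res <- list()
      for (cond in unique(tc$condition)) {
        for (rep in unique(tc$replicate[tc$condition == cond])) {
          sub <- tc[tc$condition == cond & tc$replicate == rep, ]
          cv <- loess_fit(sub$time_h, sub$rel_expr, span = tm$span,
                          grid_step = tm$grid_step, condition = cond)
          res[[length(res) + 1L]] <- data.frame(
            condition = cond, replicate = rep,
            half_max_h = cv$half_max_time, stringsAsFactors = FALSE)
        }
      }
      hm <- do.call(rbind, res)
      cmp <- compare_half_max(hm$half_max_h[hm$condition == "targeted"],
                              hm$half_max_h[hm$condition == "control"],
                              direction = tm$direction)
      hm$delay_p_value <- cmp$p_value
      wt_tsv(hm, file.path(out, "half_max_times.tsv"))
    }
  )

  for (s in pipeline_stages) {
    if (s %in% stages) run_stage(s, stage_funs[[s]])
  }
  write_manifest(manifest, out)
  invisible(manifest)
}

write_manifest <- function(manifest, out) {
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}
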