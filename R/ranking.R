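# Shadow-feature (Boruta-style) all-relevant feature selection over a
# random-forest classifier. The forest itself is delegated to ranger;
# the shadow/hit/binomial decision loop is implemented here.

# Two-sided binomial decision on `hits` out of `iters` tries at p = 0.5.
# Returns "Confirmed", "Rejected" or "Tentative".
boruta_decision <- function(hits, iters, alpha = 0.05) {
  p <- stats::binom.test(hits, iters, 0.5)$p.value
  if (p < alpha) {
    if (hits > iters / 2) "Confirmed" else "Rejected"
  } else {
    "Tentative"
  }
}

#' Shadow-feature (Boruta-style) feature ranking
#'
#' All-relevant feature selection: at each iteration every remaining
#' feature is copied and the copy's values are shuffled across samples
#' ("shadow" features), a random forest is fit on real + shadow
#' features, and a real feature scores a *hit* when its importance
#' exceeds the maximum shadow importance. After each iteration a
#' two-sided binomial test compares each undecided feature's hit count
#' against Binomial(iterations, 0.5): significantly many hits confirms
#' the feature, significantly few rejects it (and removes it from
#' subsequent iterations). Undecided features at `max_iter` are
#' Tentative. Shadows are rebuilt every iteration and can never be
#' confirmed — only real features are reported.
#'
#' Importance is the Z-score of the per-tree permutation importance
#' (mean divided by its standard error over trees, ranger's scaled
#' permutation importance); `importance = "impurity"` switches to raw
#' Gini impurity-decrease importance.
#'
#' @param X numeric matrix (samples x features), no missing values;
#'   conventionally the Z-scored gene x feature design matrix.
#' @param y class labels (factor or coercible), >= 2 classes.
#' @param max_iter maximum number of iterations (default 100).
#' @param alpha binomial-test significance level (default 0.05).
#' @param n_trees trees per forest (default 500).
#' @param importance `"permutation"` (default, scaled to a Z-score) or
#'   `"impurity"`.
#' @param seed integer seed; the run is deterministic given it.
#' @return data.frame of class `boruta_ranking`: one row per feature
#'   with `decision`, `hits`, `n_iterations` and `median_importance`
#'   (median over the iterations in which the feature was alive).
#'   The full importance history (iterations x features, NA once
#'   rejected) is in `attr(, "importance_history")`.
#' @export
boruta_rank <- function(X, y, max_iter = 100, alpha = 0.05, n_trees = 500,
                        importance = c("permutation", "impurity"),
                        seed = 1L) {
  importance <- match.arg(importance)
  X <- as.matrix(X)
  if (anyNA(X)) stopf("X must not contain missing values")
  if (is.null(colnames(X))) colnames(X) <- paste0("feat", seq_len(ncol(X)))
  y <- factor(y)
  if (nlevels(y) < 2) stopf("y must have at least 2 classes")
  if (length(y) != nrow(X)) stopf("length(y) != nrow(X)")

  feats <- colnames(X)
  p <- length(feats)
  hits <- stats::setNames(integer(p), feats)
  decision <- stats::setNames(rep("Tentative", p), feats)
  history <- matrix(NA_real_, max_iter, p, dimnames = list(NULL, feats))

  with_seed(op_seed(seed, 5L), {
    iter <- 0L
    while (iter < max_iter && any(decision == "Tentative")) {
      iter <- iter + 1L
      # rejected features leave the model; confirmed ones stay in (and
      # keep contributing shadows), only their decision is frozen
      live <- feats[decision != "Rejected"]
      undecided <- feats[decision == "Tentative"]
      Xr <- X[, live, drop = FALSE]
      Xs <- apply(Xr, 2, sample)
      if (is.null(dim(Xs))) Xs <- matrix(Xs, nrow = nrow(Xr))
      colnames(Xs) <- paste0("shadow_", live)
      dat <- data.frame(cbind(Xr, Xs), check.names = FALSE)
      dat$.y <- y
      fit <- ranger::ranger(
        dependent.variable.name = ".y", data = dat,
        num.trees = n_trees,
        importance = if (importance == "permutation") "permutation"
                     else "impurity",
        scale.permutation.importance = (importance == "permutation"),
        num.threads = 1,
        seed = sample.int(.Machine$integer.max, 1))
      imp <- fit$variable.importance
      shadow_max <- max(imp[paste0("shadow_", live)])
      real_imp <- imp[live]
      history[iter, live] <- real_imp
      hits[live] <- hits[live] + (real_imp > shadow_max)

      for (f in undecided) {
        decision[[f]] <- boruta_decision(hits[[f]], iter, alpha)
      }
    }
    med <- apply(history[seq_len(max(iter, 1L)), , drop = FALSE], 2,
                 stats::median, na.rm = TRUE)
    out <- data.frame(feature = feats,
                      decision = unname(decision),
                      hits = unname(hits),
                      n_iterations = iter,
                      median_importance = unname(med),
                      stringsAsFactors = FALSE)
    attr(out, "importance_history") <-
      history[seq_len(max(iter, 1L)), , drop = FALSE]
    class(out) <- c("boruta_ranking", "data.frame")
    out
  })
}

#' @export
print.boruta_ranking <- function(x, ...) {
  cat(sprintf("boruta_ranking: %d features, %d iteration(s)\n",
              nrow(x), x$n_iterations[1]))
  print(table(x$decision))
  invisible(as.data.frame(x))
}

#' Classification tree over regulatory features
#'
#' CART classification tree (Gini impurity) fit with `rpart` under the
#' leaf-size and complexity constraints used for the regulatory
#' hierarchy: every leaf holds at least `min_leaf` samples and splits
#' improving relative impurity by less than `complexity` are pruned.
#' When `min_leaf` exceeds half the sample the result is the root-only
#' majority-class tree.
#'
#' @param X numeric matrix (samples x features).
#' @param y class labels.
#' @param min_leaf minimum samples per leaf (default 50).
#' @param complexity rpart `cp` pruning parameter (default 0.007).
#' @return object of class `reg_tree` wrapping the `rpart` fit with a
#'   nested split `structure` (feature, threshold, class counts, kids)
#'   renderable as indented text by `print`.
#' @export
fit_decision_tree <- function(X, y, min_leaf = 50, complexity = 0.007) {
  X <- as.data.frame(as.matrix(X))
  y <- factor(y)
  dat <- X
  dat$.y <- y
  fit <- rpart::rpart(.y ~ ., data = dat, method = "class",
                      parms = list(split = "gini"),
                      control = rpart::rpart.control(
                        minbucket = min_leaf, cp = complexity, xval = 0,
                        maxcompete = 0, maxsurrogate = 0))
  structure(list(fit = fit, structure = rpart_to_list(fit, levels(y))),
            class = "reg_tree")
}

# Convert an rpart frame into a nested list of splits. With
# maxcompete = maxsurrogate = 0 the splits matrix holds exactly one row
# per internal node, in the frame's depth-first node order.
rpart_to_list <- function(fit, classes) {
  fr <- fit$frame
  counts <- fr[, "yval2", drop = TRUE]
  node_ids <- as.integer(rownames(fr))
  split_row <- cumsum(fr$var != "<leaf>")
  build <- function(id) {
    i <- match(id, node_ids)
    cnt <- if (is.matrix(counts)) counts[i, 1 + seq_along(classes)]
           else rep(NA_real_, length(classes))
    node <- list(n = fr$n[i],
                 class = classes[fr$yval[i]],
                 counts = stats::setNames(as.numeric(cnt), classes))
    if (fr$var[i] == "<leaf>") {
      node$leaf <- TRUE
      return(node)
    }
    node$leaf <- FALSE
    node$feature <- as.character(fr$var[i])
    node$threshold <- unname(fit$splits[split_row[i], "index"])
    node$left <- build(2L * id)
    node$right <- build(2L * id + 1L)
    node
  }
  build(1L)
}

#' @export
print.reg_tree <- function(x, ...) {
  render <- function(node, depth) {
    pad <- strrep("  ", depth)
    if (node$leaf) {
      cat(sprintf("%s<leaf> n=%d -> %s\n", pad, node$n, node$class))
    } else {
      cat(sprintf("%s%s < %.4g (n=%d, majority %s)\n", pad, node$feature,
                  node$threshold, node$n, node$class))
      render(node$left, depth + 1)
      render(node$right, depth + 1)
    }
  }
  render(x$structure, 0)
  invisible(x)
}

#' Per-group feature signal summaries
#'
#' Mean Z-scored signal of every feature within every gene group
#' (mean-level, trajectory or noise class) with a normal-approximation
#' 95% confidence interval. Singleton groups get an `NA` interval;
#' empty groups are omitted with a warning.
#'
#' @param Z genes x features matrix of Z-scored signal.
#' @param labels per-gene group labels.
#' @param conf confidence level (default 0.95).
#' @return data.frame `feature`, `group`, `n`, `mean`, `ci_lo`, `ci_hi`.
#' @export
group_feature_summary <- function(Z, labels, conf = 0.95) {
  Z <- as.matrix(Z)
  if (length(labels) != nrow(Z)) stopf("one label per gene required")
  groups <- unique(labels)
  q <- stats::qnorm(1 - (1 - conf) / 2)
  out <- list()
  for (g in groups) {
    idx <- which(labels == g)
    if (length(idx) == 0) {
      warning("empty group omitted: ", g)
      next
    }
    sub <- Z[idx, , drop = FALSE]
    mu <- colMeans(sub)
    se <- if (length(idx) > 1) {
      apply(sub, 2, stats::sd) / sqrt(length(idx))
    } else {
      rep(NA_real_, ncol(sub))
    }
    out[[g]] <- data.frame(feature = colnames(Z), group = g,
                           n = length(idx), mean = mu,
                           ci_lo = mu - q * se, ci_hi = mu + q * se,
                           stringsAsFactors = FALSE, row.names = NULL)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Promoter-versus-enhancer summary over confirmed features
#'
#' For each gene group, the average promoter Z-score across Boruta
#' Confirmed promoter features and the average enhancer score across
#' Confirmed enhancer features. Count-type features (number of
#' enhancers, number of ER binding sites, gene length) are excluded
#' from the averages even when confirmed.
#'
#' @param profiles a [build_regulatory_profiles()] result.
#' @param labels per-gene group labels (aligned to
#'   `rownames(profiles$features)`).
#' @param ranking a [boruta_rank()] result on the profile features.
#' @return data.frame `group`, `n`, `mean_promoter_z`,
#'   `mean_enhancer_score`, `n_promoter_features`, `n_enhancer_features`.
#' @export
promoter_vs_enhancer_summary <- function(profiles, labels, ranking) {
  stopifnot(inherits(profiles, "reg_profiles"))
  confirmed <- ranking$feature[ranking$decision == "Confirmed"]
  if (length(confirmed) == 0) stopf("no confirmed features")
  prov <- profiles$provenance
  prom <- confirmed[prov[confirmed] == "promoter"]
  enh <- confirmed[prov[confirmed] == "enhancer"]
  feats <- profiles$features
  groups <- unique(labels)
  out <- lapply(groups, function(g) {
    idx <- which(labels == g)
    data.frame(
      group = g, n = length(idx),
      mean_promoter_z = if (length(prom))
        mean(feats[idx, prom, drop = FALSE]) else NA_real_,
      mean_enhancer_score = if (length(enh))
        mean(feats[idx, enh, drop = FALSE]) else NA_real_,
      n_promoter_features = length(prom),
      n_enhancer_features = length(enh),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
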