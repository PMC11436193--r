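#' Rank-1 nearest-neighbour identification
#'
#' Assigns the probe the label of its nearest gallery feature under
#' Euclidean distance (1-NN); ties go to the lowest gallery index.
#'
#' @param gallery list of `"sparse_feature"` vectors.
#' @param labels gallery labels, same length.
#' @param probe a `"sparse_feature"`.
#' @return The predicted label.
#' @export
rank1_classify <- function(gallery, labels, probe) {
  if (!length(gallery)) stop("empty gallery", call. = FALSE)
  stopifnot(length(gallery) == length(labels))
  d <- vapply(gallery, match_distance, numeric(1), g = probe)
  labels[which.min(d)]
}

#' FAR and FRR over a threshold sweep
#'
#' Scores are distances; a pair is accepted when its distance is at or
#' below the threshold. At threshold `t`, FAR is the percentage of
#' imposter (different-identity) distances `<= t` and FRR the percentage
#' of genuine (same-identity) distances `> t`. FAR is non-decreasing and
#' FRR non-increasing in `t`.
#'
#' @param genuine,imposter numeric distance vectors (both nonempty).
#' @param thresholds optional sweep; defaults to all distinct scores plus
#'   a sentinel below the minimum.
#' @return data.frame with columns `threshold`, `FAR`, `FRR` (percent).
#' @export
far_frr <- function(genuine, imposter, thresholds = NULL) {
  if (!length(genuine) || !length(imposter))
    stop("both score sets must be nonempty", call. = FALSE)
  if (is.null(thresholds)) {
    thresholds <- sort(unique(c(genuine, imposter)))
    thresholds <- c(min(thresholds) - 1, thresholds)
  }
  gs <- sort(genuine); is <- sort(imposter)
  far <- 100 * findInterval(thresholds, is) / length(is)
  frr <- 100 * (1 - findInterval(thresholds, gs) / length(gs))
  data.frame(threshold = thresholds, FAR = far, FRR = frr)
}

#' Equal error rate of a verification score set
#'
#' Sweeps all distinct thresholds and locates the operating point where
#' the false-acceptance and false-rejection rates cross, linearly
#' interpolating between the two bracketing thresholds. Fully separated
#' score sets give exactly 0; indistinguishable ones about 50.
#'
#' @param genuine,imposter numeric distance vectors.
#' @return EER in percent.
#' @export
compute_eer <- function(genuine, imposter) {
  sweep <- far_frr(genuine, imposter)
  d <- sweep$FAR - sweep$FRR          # non-decreasing, from -100 to +100
  i <- which(d >= 0)[1]
  if (is.na(i)) return(50)            # degenerate: never crosses
  if (d[i] == 0 || i == 1L) return(sweep$FAR[i])
  a <- -d[i - 1] / (d[i] - d[i - 1])
  far <- sweep$FAR[i - 1] + a * (sweep$FAR[i] - sweep$FAR[i - 1])
  frr <- sweep$FRR[i - 1] + a * (sweep$FRR[i] - sweep$FRR[i - 1])
  (far + frr) / 2
}

#' Class-disjoint open-set split
#'
#' Splits by identity, never by sample: a finger's images are all in
#' training or all in testing, so evaluation identities are unseen during
#' filter selection. Deterministic for a given seed.
#'
#' @param labels vector of class labels (one per sample).
#' @param train_fraction fraction of classes assigned to training.
#' @param seed integer RNG seed.
#' @return List with `train_classes`, `test_classes` (disjoint, covering
#'   all classes).
#' @export
open_set_split <- function(labels, train_fraction = 0.5, seed = 1L) {
  classes <- sort(unique(labels))
  if (length(classes) < 2L) stop("need at least two classes", call. = FALSE)
  n_train <- max(1L, min(length(classes) - 1L,
                         round(train_fraction * length(classes))))
  train <- with_seed(seed, sort(sample(classes, n_train)))
  list(train_classes = train,
       test_classes = setdiff(classes, train))
}

# Pairwise distance matrix for a list of sparse features.
pairwise_distances <- function(features) {
  n <- length(features)
  D <- matrix(0, n, n)
  if (n < 2L) return(D)
  norms <- vapply(features, function(f) sum(f$count^2), numeric(1))
  for (i in seq_len(n - 1L)) {
    fi <- features[[i]]
    for (j in (i + 1L):n) {
      gj <- features[[j]]
      m <- match(fi$index, gj$index)
      dot <- sum(fi$count[!is.na(m)] * gj$count[m[!is.na(m)]])
      D[i, j] <- D[j, i] <- sqrt(max(norms[i] + norms[j] - 2 * dot, 0))
    }
  }
  D
}

#' Open-set recognition evaluation
#'
#' Runs the full protocol: per iteration, identities are split
#' class-disjointly, the feature extractor is fitted on the training
#' identities' images only (unsupervised), features are extracted for the
#' test identities, verification scores are formed from all intra-class
#' (genuine) and inter-class (imposter) test pairs — imposters uniformly
#' subsampled beyond `pair_budget` — and the EER is computed. Rank-1
#' accuracy uses leave-one-out 1-NN over the test set. Reported EER/ACC
#' are means over iterations.
#'
#' @param images list of ROI matrices.
#' @param labels class labels, one per image.
#' @param config an [lg_config()].
#' @param per_scale_counts diamond counts passed to [vfdcn()].
#' @param block_shape histogram block shape.
#' @param train_fraction fraction of identities used for filter selection.
#' @param n_iterations number of random splits averaged (default 5).
#' @param seed base RNG seed; iteration `i` uses a seed derived from it.
#' @param pair_budget maximum number of imposter pairs scored per
#'   iteration.
#' @param relearn_layer2 passed to [vfdcn()].
#' @return Object of class `"vfdcn_eval"`: list with `EER`, `ACC`
#'   (percent, means), `per_iteration` data.frame, `roc` (threshold/FAR/FRR
#'   sweep of the first iteration), `n_genuine`, `n_imposter`, `seed`,
#'   `n_iterations`.
#' @examples
#' \donttest{
#' spec <- synth_spec(n_classes = 6, samples_per_class = 4)
#' ds <- synth_images(spec)
#' cfg <- lg_config(Nscale = 2, Nori = 6, image_shape = c(32, 32))
#' evaluate_recognition(ds$images, ds$labels, cfg,
#'                      per_scale_counts = c(2, 3), n_iterations = 1)
#' }
#' @export
evaluate_recognition <- function(images, labels, config = lg_config(),
                                 per_scale_counts = c(2L, 7L, 7L, 2L),
                                 block_shape = c(8L, 8L),
                                 train_fraction = 0.5, n_iterations = 5L,
                                 seed = 1L, pair_budget = 1e6,
                                 relearn_layer2 = FALSE) {
  stopifnot(length(images) == length(labels), length(images) >= 4L)
  iters <- vector("list", n_iterations)
  roc <- NULL; ng <- ni <- NA_integer_
  for (it in seq_len(n_iterations)) {
    it_seed <- derive_seed(seed, it)
    sp <- open_set_split(labels, train_fraction, seed = it_seed)
    tr <- which(labels %in% sp$train_classes)
    te <- which(labels %in% sp$test_classes)
    if (length(unique(labels[te])) < 2L)
      stop("test split has fewer than two classes", call. = FALSE)
    model <- vfdcn(images[tr], config, per_scale_counts, block_shape,
                   relearn_layer2 = relearn_layer2)
    feats <- lapply(images[te], extract_feature, model = model)
    lab <- labels[te]
    D <- pairwise_distances(feats)
    ut <- which(upper.tri(D), arr.ind = TRUE)
    same <- lab[ut[, 1]] == lab[ut[, 2]]
    genuine <- D[ut[same, , drop = FALSE]]
    imposter <- D[ut[!same, , drop = FALSE]]
    if (length(imposter) > pair_budget) {
      keep <- with_seed(derive_seed(it_seed, 7L),
                        sample.int(length(imposter), pair_budget))
      imposter <- imposter[keep]
    }
    eer <- compute_eer(genuine, imposter)
    # leave-one-out rank-1: nearest other test sample's label
    Dl <- D; diag(Dl) <- Inf
    pred <- lab[apply(Dl, 1, which.min)]
    acc <- 100 * mean(pred == lab)
    iters[[it]] <- data.frame(iteration = it, EER = eer, ACC = acc,
                              n_test = length(te))
    if (it == 1L) {
      roc <- far_frr(genuine, imposter)
      ng <- length(genuine); ni <- length(imposter)
    }
  }
  per_it <- do.call(rbind, iters)
  structure(list(EER = mean(per_it$EER), ACC = mean(per_it$ACC),
                 per_iteration = per_it, roc = roc,
                 n_genuine = ng, n_imposter = ni,
                 seed = seed, n_iterations = n_iterations),
            class = "vfdcn_eval")
}

#' @export
print.vfdcn_eval <- function(x, ...) {
  cat("Open-set recognition evaluation\n")
  cat(sprintf("  EER: %.2f%%   rank-1 ACC: %.2f%%  (mean of %d iteration%s)\n",
              x$EER, x$ACC, x$n_iterations, if (x$n_iterations > 1) "s" else ""))
  cat(sprintf("  first split: %d genuine / %d imposter pairs\n",
              x$n_genuine, x$n_imposter))
  invisible(x)
}

#' ROC curve of an evaluation report
#'
#' Plots the genuine accept rate (100 - FRR) against FAR over the
#' threshold sweep; the curve runs from (0, 0) to (100, 100).
#'
#' @param x a `"vfdcn_eval"`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.vfdcn_eval <- function(x, ...) {
  graphics::plot(x$roc$FAR, 100 - x$roc$FRR, type = "l",
                 xlab = "FAR (%)", ylab = "GAR (%)",
                 main = sprintf("ROC (EER = %.2f%%)", x$EER), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' One-parameter performance sweep
#'
#' Re-runs [evaluate_recognition()] over a grid of values for exactly one
#' of the filter parameters `Wmin`, `M`, `T` — or over a list of diamond
#' configurations — holding everything else fixed.
#'
#' @param images,labels dataset as in [evaluate_recognition()].
#' @param parameter one of `"Wmin"`, `"M"`, `"T"`, `"diamond"`.
#' @param values numeric vector, or for `"diamond"` a list of per-scale
#'   count vectors.
#' @param config baseline [lg_config()].
#' @param ... further arguments to [evaluate_recognition()].
#' @return data.frame with one row per grid point: `parameter`, `value`,
#'   `EER`, `ACC`.
#' @export
run_sweep <- function(images, labels, parameter, values,
                      config = lg_config(), ...) {
  parameter <- match.arg(parameter, c("Wmin", "M", "T", "diamond"))
  args <- list(...)
  counts <- if (!is.null(args$per_scale_counts)) args$per_scale_counts
  else c(2L, 7L, 7L, 2L)
  args$per_scale_counts <- NULL
  rows <- vector("list", length(values))
  vals <- if (parameter == "diamond") values else as.list(values)
  for (i in seq_along(vals)) {
    cfg <- config
    pc <- counts
    if (parameter == "diamond") pc <- vals[[i]]
    else {
      field <- c(Wmin = "Wmin", M = "M", T = "T_ang")[[parameter]]
      cfg[[field]] <- vals[[i]]
      cfg <- do.call(lg_config, cfg[c("Wmin", "M", "T_ang", "sigma_r",
                                      "Nscale", "Nori", "image_shape")])
    }
    rep <- do.call(evaluate_recognition,
                   c(list(images = images, labels = labels, config = cfg,
                          per_scale_counts = pc), args))
    rows[[i]] <- data.frame(
      parameter = parameter,
      value = if (parameter == "diamond")
        paste0("[", paste(vals[[i]], collapse = ","), "]")
      else vals[[i]],
      EER = rep$EER, ACC = rep$ACC)
  }
  do.call(rbind, rows)
}
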