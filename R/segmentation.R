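#' Segmentation pipeline configuration
#'
#' The ensemble searches LWIFCM's initial centers together with its
#' uncertainty parameter `alpha` and fuzzifier `m` using the chameleon swarm,
#' then re-runs LWIFCM to convergence from the winning candidate.
#'
#' @param c number of clusters (default 4: background, two tissues, tumor).
#' @param pop_size,iterations chameleon swarm budget.
#' @param alpha_range search interval for `alpha`, inside `(0, 1]`.
#' @param m_range search interval for the fuzzifier `m` (above 1).
#' @param lwifcm an [lwifcm_config()] holding the inner clustering settings
#'   (its `c`, `alpha`, `m` are overridden by the search).
#' @param fitness_iter LWIFCM iteration cap inside the swarm's fitness
#'   evaluation (full convergence there would be wasteful).
#' @param fitness `"reference"` (default) scores the centers a candidate's
#'   capped run reaches with a fixed-reference fuzzy c-means objective
#'   (fuzzifier 2), making candidates with different `(alpha, m)`
#'   comparable; `"objective"` scores the candidate's own final objective,
#'   whose scale depends on `m` (larger fuzzifiers shrink it for any
#'   centers, which biases the search toward the `m` bound).
#' @param seed RNG seed.
#' @return object of class `segmentation_config`.
#' @export
segmentation_config <- function(c = 4L, pop_size = 10L, iterations = 15L,
                                alpha_range = c(0.5, 1), m_range = c(1.5, 3),
                                lwifcm = lwifcm_config(), fitness_iter = 10L,
                                fitness = c("reference", "objective"),
                                seed = 1L) {
  fitness <- match.arg(fitness)
  if (c < 2) abort("c must be >= 2")
  if (alpha_range[1] <= 0 || alpha_range[2] > 1 ||
      alpha_range[1] > alpha_range[2])
    abort("alpha_range must lie within (0, 1]")
  if (m_range[1] <= 1 || m_range[1] > m_range[2])
    abort("m_range must lie above 1")
  structure(list(c = as.integer(c), pop_size = as.integer(pop_size),
                 iterations = as.integer(iterations),
                 alpha_range = as.numeric(alpha_range),
                 m_range = as.numeric(m_range), lwifcm = lwifcm,
                 fitness_iter = as.integer(fitness_iter),
                 fitness = fitness,
                 seed = as.integer(seed)),
            class = "segmentation_config")
}

#' Encode the swarm search space for a segmentation candidate
#'
#' A candidate is the vector `[v_1, ..., v_c, alpha, m]`: `c` intensity
#' centers bounded by the observed intensity range, then the two clustering
#' parameters bounded by their configured ranges.
#'
#' @param c number of clusters.
#' @param data_range length-2 observed intensity range.
#' @param alpha_range,m_range parameter search intervals.
#' @return list with `lower` and `upper` bound vectors of length `c + 2`.
#' @export
encode_candidate <- function(c, data_range, alpha_range = c(0.5, 1),
                             m_range = c(1.5, 3)) {
  if (c < 2) abort("c must be >= 2")
  list(lower = c(rep(data_range[1], c), alpha_range[1], m_range[1]),
       upper = c(rep(data_range[2], c), alpha_range[2], m_range[2]))
}

#' Decode a swarm candidate
#' @param x numeric vector of length `c + 2`.
#' @param c number of clusters.
#' @return list with `centers` (sorted ascending), `alpha`, `m`.
#' @export
decode_candidate <- function(x, c) {
  list(centers = x[seq_len(c)], alpha = x[c + 1L], m = x[c + 2L])
}

#' Swarm fitness of a segmentation candidate
#'
#' Runs LWIFCM for a capped number of iterations from the candidate's
#' centers and `(alpha, m)`, then scores the result (lower is better)
#' according to `config$fitness`: by default the reached centers are scored
#' with a fixed-reference fuzzy c-means objective so that candidates with
#' different fuzzifiers are comparable. Candidates with coincident centers
#' get a large finite penalty rather than an error.
#'
#' @param candidate numeric vector `[v_1..v_c, alpha, m]`.
#' @param image preprocessed intensity raster.
#' @param config a [segmentation_config()].
#' @return scalar fitness.
#' @export
csa_fitness <- function(candidate, image, config) {
  dec <- decode_candidate(candidate, config$c)
  if (min(dist(dec$centers)) < 1e-6 * (max(image) - min(image) + 1e-12))
    return(1e9 + sum(candidate^2))
  cfg <- config$lwifcm
  cfg$c <- config$c
  cfg$alpha <- dec$alpha
  cfg$m <- dec$m
  cfg$max_iter <- config$fitness_iter
  fit <- run_lwifcm(image, cfg, matrix(dec$centers, ncol = 1L), image = TRUE)
  if (config$fitness == "objective") return(fit$model$objective)
  # reference scoring: plain FCM objective of the reached centers at m = 2
  x <- matrix(as.vector(image), ncol = 1L)
  U <- update_memberships(x, fit$model$V, 2)
  sum(U^2 * sq_dist(x, as_center_matrix(fit$model$V, 1L)))
}

#' Segment an image with swarm-optimized LWIFCM
#'
#' The chameleon swarm minimizes the capped-run LWIFCM objective over
#' initial centers and `(alpha, m)`; the winner is refined by a full LWIFCM
#' run to convergence. Labels are the argmax of the modified memberships,
#' reported 0-based.
#'
#' @param image preprocessed intensity raster in `[0, 1]`.
#' @param config a [segmentation_config()].
#' @param truth optional integer ground-truth raster; when given, predicted
#'   labels are matched to truth by [match_labels()] and per-class Dice/IoU
#'   are reported.
#' @return list with `label_map` (integer raster, labels in `0:(c-1)`),
#'   `centers`, `alpha`, `m`, `objective`, `history`, and when `truth` is
#'   given `matching` plus a `scores` data frame of per-class Dice/IoU.
#' @export
segment_image <- function(image, config = segmentation_config(), truth = NULL) {
  check_gray_image(image)
  bounds <- encode_candidate(config$c, range(image),
                             config$alpha_range, config$m_range)
  csa <- csa_config(pop_size = config$pop_size, dims = config$c + 2L,
                    lower = bounds$lower, upper = bounds$upper,
                    iterations = config$iterations,
                    seed = child_seed(config$seed, 1L))
  opt <- csa_minimize(function(x) csa_fitness(x, image, config), csa)
  dec <- decode_candidate(opt$best_x, config$c)
  cfg <- config$lwifcm
  cfg$c <- config$c
  cfg$alpha <- dec$alpha
  cfg$m <- dec$m
  centers <- sort(dec$centers)
  fit <- run_lwifcm(image, cfg, matrix(centers, ncol = 1L), image = TRUE)
  label_map <- fit$labels - 1L
  out <- list(label_map = label_map, centers = as.numeric(fit$model$V),
              alpha = dec$alpha, m = dec$m,
              objective = fit$model$objective, history = opt$history)
  if (!is.null(truth)) {
    perm <- match_labels(label_map, truth)
    scores <- lapply(seq_along(perm), function(i) {
      tl <- perm[i]
      if (is.na(tl)) return(NULL)
      s <- dice_iou(label_map == as.integer(names(perm)[i]), truth == tl)
      data.frame(pred_label = as.integer(names(perm)[i]), truth_label = tl,
                 dice = s$dice, iou = s$iou)
    })
    out$matching <- perm
    out$scores <- do.call(rbind, scores)
  }
  out
}

#' Match arbitrary cluster labels to ground-truth labels
#'
#' Greedy maximum-overlap one-to-one assignment: the largest cell of the
#' predicted-vs-truth contingency table is matched first, its row and column
#' removed, and so on. Unmatched predicted labels map to `NA`.
#'
#' @param pred,truth integer label rasters of identical shape.
#' @return named integer vector: names are predicted labels, values the
#'   matched truth labels.
#' @export
match_labels <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth))) abort("label rasters differ in shape")
  pl <- sort(unique(as.vector(pred)))
  tl <- sort(unique(as.vector(truth)))
  tab <- table(factor(as.vector(pred), levels = pl),
               factor(as.vector(truth), levels = tl))
  perm <- stats::setNames(rep(NA_integer_, length(pl)), pl)
  tab <- matrix(as.numeric(tab), length(pl), length(tl),
                dimnames = list(pl, tl))
  while (any(is.finite(tab)) && max(tab, na.rm = TRUE) >= 0) {
    ij <- which(tab == max(tab), arr.ind = TRUE)[1L, ]
    perm[rownames(tab)[ij[1L]]] <- as.integer(colnames(tab)[ij[2L]])
    tab <- tab[-ij[1L], -ij[2L], drop = FALSE]
    if (nrow(tab) == 0 || ncol(tab) == 0) break
  }
  perm
}
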