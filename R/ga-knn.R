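# Genetic-algorithm feature selection wrapping a k-nearest-neighbor
# classifier -- the curative-efficacy model at the centre of the package.

#' Genetic-algorithm search parameters
#'
#' The published model reports only the cross-validation scheme (omit 20%,
#' 10 iterations) and that the neighbor count k was tuned; every other
#' hyperparameter here is a package default chosen for a small search space
#' (at most ~44 peaks).
#'
#' @param population_size individuals per generation.
#' @param generations number of generations.
#' @param crossover_rate probability a pair is recombined (uniform crossover).
#' @param mutation_rate per-gene flip probability.
#' @param tournament_size tournament selection size.
#' @param elitism_count elite individuals copied unchanged each generation.
#' @param max_panel_size largest allowed peak panel.
#' @param k_candidates odd neighbor counts the GA may pick from.
#' @param holdout_fraction fraction omitted per cross-validation iteration.
#' @param holdout_iterations number of random stratified holdouts.
#' @param seed integer seed; fixes the holdout schedule and the whole run.
#' @return a list of class `ga_config`.
#' @export
ga_config <- function(population_size = 64L, generations = 50L,
                      crossover_rate = 0.9, mutation_rate = 0.05,
                      tournament_size = 3L, elitism_count = 2L,
                      max_panel_size = 8L, k_candidates = c(1L, 3L, 5L, 7L, 9L),
                      holdout_fraction = 0.2, holdout_iterations = 10L,
                      seed = NULL) {
  stopifnot(population_size > elitism_count, generations >= 1,
            crossover_rate >= 0, crossover_rate <= 1,
            mutation_rate >= 0, mutation_rate <= 1,
            max_panel_size >= 1, all(k_candidates %% 2 == 1),
            holdout_fraction > 0, holdout_fraction < 1, holdout_iterations >= 1)
  structure(list(population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 crossover_rate = crossover_rate, mutation_rate = mutation_rate,
                 tournament_size = as.integer(tournament_size),
                 elitism_count = as.integer(elitism_count),
                 max_panel_size = as.integer(max_panel_size),
                 k_candidates = as.integer(k_candidates),
                 holdout_fraction = holdout_fraction,
                 holdout_iterations = as.integer(holdout_iterations),
                 seed = seed),
            class = "ga_config")
}

# z-score standardization fit on training features; constant features get
# unit scale so they contribute nothing to distances.
fit_standardization <- function(x) {
  mu <- colMeans(x)
  sg <- apply(x, 2, stats::sd)
  sg[!is.finite(sg) | sg == 0] <- 1
  list(mean = mu, sd = sg)
}

apply_standardization <- function(x, std) {
  sweep(sweep(x, 2, std$mean, "-"), 2, std$sd, "/")
}

# kNN with majority vote among the k nearest training rows (Euclidean on
# already-standardized features); vote ties fall back to the single nearest
# neighbor. Distance ties are broken by training-row order (stable).
knn_classify <- function(train, labels, query, k) {
  k <- min(k, nrow(train))
  d2 <- outer(rowSums(query^2), rep(1, nrow(train))) +
    outer(rep(1, nrow(query)), rowSums(train^2)) - 2 * query %*% t(train)
  vapply(seq_len(nrow(query)), function(i) {
    nn <- order(d2[i, ])[seq_len(k)]
    votes <- table(labels[nn])
    top <- names(votes)[votes == max(votes)]
    if (length(top) == 1L) top else labels[nn[1L]]
  }, "")
}

# Stratified random holdout index sets, one per iteration, fixed by `seed`:
# the schedule every candidate model is scored on.
make_holdout_splits <- function(labels, fraction, iterations, seed = NULL) {
  with_seed(seed, lapply(seq_len(iterations), function(i) {
    unlist(lapply(unique(labels), function(g) {
      idx <- which(labels == g)
      n_out <- max(1L, round(fraction * length(idx)))
      if (n_out >= length(idx)) stop("holdout would exhaust a class")
      sample(idx, n_out)
    }), use.names = FALSE)
  }))
}

#' Repeated stratified-holdout cross-validation of a peak panel
#'
#' The published reliability measure: for each iteration a stratified 20%
#' of training samples is held out, feature standardization is refit on the
#' remainder, and the holdout is classified by kNN; the cross-validation
#' rate is the mean percent correct. The recognition rate is resubstitution
#' accuracy of the model fit on the full training set.
#'
#' @param x numeric area matrix (samples x peaks) or a labeled
#'   [peak_matrix()].
#' @param labels group labels (ignored when `x` is a `peak_matrix`).
#' @param panel integer column indices of the peaks to use.
#' @param k neighbor count.
#' @param holdout_fraction,holdout_iterations the published 20% / 10 scheme.
#' @param seed seed fixing the holdout schedule.
#' @param splits precomputed holdout index sets (overrides `seed`), as used
#'   inside the GA so all candidates see identical splits.
#' @return a list of class `cv_report`: `cross_validation_rate`,
#'   `recognition_rate` (both percent), `per_iteration_rates`.
#' @export
cross_validate <- function(x, labels = NULL, panel = NULL, k = 5L,
                           holdout_fraction = 0.2, holdout_iterations = 10L,
                           seed = NULL, splits = NULL) {
  if (inherits(x, "peak_matrix")) {
    keep <- x$group %in% c("response", "progression")
    labels <- x$group[keep]
    x <- x$areas[keep, , drop = FALSE]
  }
  x <- as.matrix(x)
  if (is.null(panel)) panel <- seq_len(ncol(x))
  if (nrow(x) < 5L) stop("need at least 5 training samples")
  if (is.null(splits))
    splits <- make_holdout_splits(labels, holdout_fraction, holdout_iterations, seed)
  xs <- x[, panel, drop = FALSE]
  per <- vapply(splits, function(out) {
    tr <- xs[-out, , drop = FALSE]
    if (length(unique(labels[-out])) < 2L) stop("a holdout remainder lost a class")
    std <- fit_standardization(tr)
    pred <- knn_classify(apply_standardization(tr, std), labels[-out],
                         apply_standardization(xs[out, , drop = FALSE], std), k)
    100 * mean(pred == labels[out])
  }, 0)
  std <- fit_standardization(xs)
  z <- apply_standardization(xs, std)
  recog <- 100 * mean(knn_classify(z, labels, z, k) == labels)
  structure(list(cross_validation_rate = mean(per), recognition_rate = recog,
                 per_iteration_rates = per),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("Cross-validation rate: %.2f%%  (over %d holdouts)\nRecognition rate:      %.2f%%\n",
              x$cross_validation_rate, length(x$per_iteration_rates),
              x$recognition_rate))
  invisible(x)
}

# Mean holdout accuracy only (no resubstitution pass): the hot path inside
# the GA fitness loop.
cv_rate <- function(x, labels, panel, k, splits) {
  xs <- x[, panel, drop = FALSE]
  mean(vapply(splits, function(out) {
    tr <- xs[-out, , drop = FALSE]
    std <- fit_standardization(tr)
    pred <- knn_classify(apply_standardization(tr, std), labels[-out],
                         apply_standardization(xs[out, , drop = FALSE], std), k)
    100 * mean(pred == labels[out])
  }, 0))
}

# Shared fitness machinery: memoized CV rate for a (feature subset, k) pair
# on a fixed split schedule.
make_fitness <- function(x, labels, splits) {
  memo <- new.env(parent = emptyenv())
  function(panel, k) {
    key <- paste(c(k, panel), collapse = ",")
    if (!is.null(memo[[key]])) return(memo[[key]])
    f <- cv_rate(x, labels, panel, k, splits)
    memo[[key]] <- f
    f
  }
}

repair_genome <- function(bits, max_panel) {
  on <- which(bits)
  if (length(on) == 0L) bits[sample.int(length(bits), 1L)] <- TRUE
  else if (length(on) > max_panel) bits[sample(on, length(on) - max_panel)] <- FALSE
  bits
}

#' Fit the GA-selected kNN curative-efficacy classifier
#'
#' Chromosomes encode a peak subset (at most `max_panel_size` peaks) and a
#' neighbor count k; fitness is the repeated stratified-holdout
#' cross-validation rate on a split schedule fixed once per run, so all
#' individuals are compared on identical holdouts. A standard generational
#' GA (tournament selection, uniform crossover, per-gene mutation, elitism)
#' searches the space; the best individual is refit on the full training
#' set and returned.
#'
#' @param x a labeled [peak_matrix()], or a numeric samples x peaks matrix.
#' @param labels group labels when `x` is a bare matrix.
#' @param config a [ga_config()]; `config$seed` makes the run deterministic.
#' @return an object of class `ga_knn`: `selected_mz`, `selected_idx`, `k`,
#'   `training_areas` (selected columns), `training_labels`,
#'   `standardization`, `cv_report`, `history` (per-generation best/mean
#'   fitness), `config`.
#' @seealso [predict.ga_knn()], [cross_validate()], [exhaustive_select()]
#' @export
#' @examples
#' pm <- simulate_peak_table(seed = 7)
#' fit <- ga_knn(pm, config = ga_config(population_size = 16, generations = 5, seed = 7))
#' fit
ga_knn <- function(x, labels = NULL, config = ga_config()) {
  if (inherits(x, "peak_matrix")) {
    keep <- x$group %in% c("response", "progression")
    labels <- x$group[keep]
    mzs <- x$reference_mz
    x <- x$areas[keep, , drop = FALSE]
  } else {
    x <- as.matrix(x)
    mzs <- if (!is.null(colnames(x))) suppressWarnings(as.numeric(colnames(x))) else seq_len(ncol(x))
  }
  p <- ncol(x)
  if (p < 1L) stop("empty peak panel")
  if (length(unique(labels)) < 2L) stop("training labels must contain both groups")
  cfg <- config
  with_seed(cfg$seed, {
    splits <- make_holdout_splits(labels, cfg$holdout_fraction,
                                  cfg$holdout_iterations, seed = NULL)
    fitness <- make_fitness(x, labels, splits)
    # initial population: random panels of size 1..max_panel_size
    pop <- lapply(seq_len(cfg$population_size), function(i) {
      sz <- sample.int(min(cfg$max_panel_size, p), 1L)
      bits <- rep(FALSE, p)
      bits[sample.int(p, sz)] <- TRUE
      list(bits = bits, k = sample(cfg$k_candidates, 1L))
    })
    history <- data.frame(generation = integer(0), best = numeric(0), mean = numeric(0))
    # selection score = fitness with a tie-break toward smaller panels; the
    # epsilon is far below the fitness granularity (one holdout sample
    # changes the rate by >= 0.5%), so it only resolves exact ties
    score_of <- function(g, f) f - 1e-6 * sum(g$bits)
    fits <- vapply(pop, function(g) fitness(which(g$bits), g$k), 0)
    scores <- mapply(score_of, pop, fits)
    for (gen in seq_len(cfg$generations)) {
      elite <- order(-scores)[seq_len(cfg$elitism_count)]
      newpop <- pop[elite]
      while (length(newpop) < cfg$population_size) {
        pick <- function() {
          cand <- sample.int(cfg$population_size, cfg$tournament_size)
          pop[[cand[which.max(scores[cand])]]]
        }
        pa <- pick(); pb <- pick()
        child <- pa
        if (stats::runif(1) < cfg$crossover_rate) {
          take <- stats::runif(p) < 0.5
          child$bits <- ifelse(take, pa$bits, pb$bits)
          if (stats::runif(1) < 0.5) child$k <- pb$k
        }
        flip <- stats::runif(p) < cfg$mutation_rate
        child$bits <- xor(child$bits, flip)
        if (stats::runif(1) < cfg$mutation_rate) child$k <- sample(cfg$k_candidates, 1L)
        child$bits <- repair_genome(child$bits, cfg$max_panel_size)
        newpop[[length(newpop) + 1L]] <- child
      }
      pop <- newpop
      fits <- vapply(pop, function(g) fitness(which(g$bits), g$k), 0)
      scores <- mapply(score_of, pop, fits)
      history <- rbind(history, data.frame(generation = gen,
                                           best = max(fits), mean = mean(fits)))
    }
    best <- pop[[which.max(scores)]]
    idx <- which(best$bits)
    cvr <- cross_validate(x, labels, panel = idx, k = best$k, splits = splits)
    xs <- x[, idx, drop = FALSE]
    structure(list(selected_mz = mzs[idx], selected_idx = idx, k = best$k,
                   training_areas = xs, training_labels = labels,
                   standardization = fit_standardization(xs),
                   cv_report = cvr, history = history, config = cfg),
              class = "ga_knn")
  })
}

#' Exhaustive search over small peak panels
#'
#' Brute-force counterpart of [ga_knn()]: evaluates every feature subset up
#' to `max_panel_size` crossed with every k on the identical fixed holdout
#' schedule, and returns the best. Used as the independent optimality
#' oracle for the GA on small panels.
#'
#' @inheritParams ga_knn
#' @param max_panel_size largest subset enumerated.
#' @param k_candidates neighbor counts enumerated.
#' @param holdout_fraction,holdout_iterations,seed as in [ga_config()];
#'   `seed` must match the `ga_knn` run being compared.
#' @return a list: `best_fitness`, `best_panel` (column indices), `best_k`,
#'   and `n_evaluated`.
#' @export
exhaustive_select <- function(x, labels = NULL, max_panel_size = 3L,
                              k_candidates = c(1L, 3L, 5L),
                              holdout_fraction = 0.2, holdout_iterations = 10L,
                              seed = NULL) {
  if (inherits(x, "peak_matrix")) {
    keep <- x$group %in% c("response", "progression")
    labels <- x$group[keep]
    x <- x$areas[keep, , drop = FALSE]
  }
  x <- as.matrix(x)
  with_seed(seed, {
    splits <- make_holdout_splits(labels, holdout_fraction, holdout_iterations,
                                  seed = NULL)
    fitness <- make_fitness(x, labels, splits)
    best <- list(best_fitness = -Inf, best_panel = integer(0), best_k = NA_integer_,
                 n_evaluated = 0L)
    for (sz in seq_len(min(max_panel_size, ncol(x)))) {
      combos <- utils::combn(ncol(x), sz)
      for (ci in seq_len(ncol(combos))) {
        for (k in k_candidates) {
          f <- fitness(combos[, ci], k)
          best$n_evaluated <- best$n_evaluated + 1L
          if (f > best$best_fitness) {
            best$best_fitness <- f
            best$best_panel <- combos[, ci]
            best$best_k <- k
          }
        }
      }
    }
    best
  })
}

#' Nearest-centroid classifier
#'
#' A transparent stand-in for the proprietary "quick classifier" style
#' baseline: each class is summarized by its mean standardized feature
#' vector and a sample takes the label of the nearer centroid; an exact
#' midpoint goes to the response class by convention.
#'
#' @inheritParams ga_knn
#' @param panel optional integer column indices restricting the features.
#' @return an object of class `centroid_clf`.
#' @export
fit_centroid <- function(x, labels = NULL, panel = NULL) {
  if (inherits(x, "peak_matrix")) {
    keep <- x$group %in% c("response", "progression")
    labels <- x$group[keep]
    mzs <- x$reference_mz
    x <- x$areas[keep, , drop = FALSE]
  } else {
    x <- as.matrix(x)
    mzs <- if (!is.null(colnames(x))) suppressWarnings(as.numeric(colnames(x))) else seq_len(ncol(x))
  }
  if (is.null(panel)) panel <- seq_len(ncol(x))
  xs <- x[, panel, drop = FALSE]
  std <- fit_standardization(xs)
  z <- apply_standardization(xs, std)
  cents <- rbind(response = colMeans(z[labels == "response", , drop = FALSE]),
                 progression = colMeans(z[labels == "progression", , drop = FALSE]))
  structure(list(selected_mz = mzs[panel], selected_idx = panel,
                 centroids = cents, standardization = std),
            class = "centroid_clf")
}

#' @rdname fit_centroid
#' @param object a fitted `centroid_clf`.
#' @param newdata a [peak_matrix()] or numeric matrix with the model's peaks.
#' @param ... unused.
#' @export
predict.centroid_clf <- function(object, newdata, ...) {
  q <- extract_model_features(object, newdata)
  z <- apply_standardization(q, object$standardization)
  d_r <- rowSums(sweep(z, 2, object$centroids["response", ], "-")^2)
  d_p <- rowSums(sweep(z, 2, object$centroids["progression", ], "-")^2)
  ifelse(d_p < d_r, "progression", "response")   # midpoint -> response
}

# Match a model's selected m/z values against the columns of new data
# (within relative tolerance) and return the feature submatrix.
extract_model_features <- function(object, newdata, tolerance = 0.002) {
  if (inherits(newdata, "peak_matrix")) {
    idx <- vapply(object$selected_mz, function(m) {
      j <- which.min(abs(newdata$reference_mz - m))
      if (abs(newdata$reference_mz[j] - m) > tolerance * m)
        stop(sprintf("model peak m/z %.2f not matched in new data", m))
      j
    }, 1L)
    newdata$areas[, idx, drop = FALSE]
  } else {
    newdata <- as.matrix(newdata)
    if (ncol(newdata) == length(object$selected_mz)) return(newdata)
    newdata[, object$selected_idx, drop = FALSE]
  }
}
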