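#' Assemble a feature matrix for sensitivity classification
#'
#' Joins per-row feature sources by id: G/C content computed from sequence
#' as `(G + C) / length`, a nuclear-speckle proximity score (mean SON
#' TSA-seq), per-RBP occupancy columns, and any precomputed extras (e.g.
#' G-quadruplex density in intron mode). Transcript mode adds the median
#' intron length when an intron table is supplied. Missing feature values
#' are median-imputed and counted in the imputation log.
#'
#' @param annotation data frame with `row_id` and `length`.
#' @param sequences named character vector of sequences (names = row ids);
#'   optional.
#' @param speckle named numeric vector of speckle proximity scores; optional.
#' @param occupancy numeric matrix (rows = row ids) of RBP occupancy;
#'   optional.
#' @param introns data frame with `transcript_id`, `length` for the median
#'   intron length feature (transcript mode); optional.
#' @param extra data frame with `row_id` plus numeric columns passed
#'   through; optional.
#' @param mode `"transcript"` or `"intron"`.
#' @return data frame keyed by `row_id` with numeric feature columns and an
#'   `"imputation_log"` attribute (named count of imputed values per
#'   column).
#' @export
assemble_features <- function(annotation, sequences = NULL, speckle = NULL,
                              occupancy = NULL, introns = NULL, extra = NULL,
                              mode = c("transcript", "intron")) {
  mode <- match.arg(mode)
  if (is.null(annotation$row_id)) stop("annotation must carry row_id")
  fm <- data.frame(row_id = annotation$row_id, length = annotation$length,
                   stringsAsFactors = FALSE)
  if (!is.null(sequences)) {
    if (!all(fm$row_id %in% names(sequences))) {
      miss <- setdiff(fm$row_id, names(sequences))[1]
      stop("row absent from sequence source: ", miss)
    }
    s <- toupper(sequences[fm$row_id])
    gc <- (nchar(gsub("[^GC]", "", s))) / nchar(s)
    fm$gc_content <- gc
  }
  if (!is.null(introns) && mode == "transcript") {
    med <- tapply(introns$length, introns$transcript_id, stats::median)
    fm$median_intron_length <- as.numeric(med[fm$row_id])
  }
  if (!is.null(speckle)) fm$speckle_score <- as.numeric(speckle[fm$row_id])
  if (!is.null(occupancy)) {
    occ <- as.matrix(occupancy)
    m <- occ[match(fm$row_id, rownames(occ)), , drop = FALSE]
    colnames(m) <- paste0("occ_", colnames(occ))
    fm <- cbind(fm, as.data.frame(m))
  }
  if (!is.null(extra)) {
    fm <- merge(fm, extra, by = "row_id", all.x = TRUE, sort = FALSE)
  }
  num_cols <- setdiff(names(fm), "row_id")
  imput <- integer(0)
  for (cn in num_cols) {
    na <- is.na(fm[[cn]])
    if (any(na)) {
      fm[[cn]][na] <- stats::median(fm[[cn]], na.rm = TRUE)
      imput[cn] <- sum(na)
    }
  }
  attr(fm, "imputation_log") <- imput
  rownames(fm) <- NULL
  fm
}

# Oversample the minority class by random duplication to exact parity.
oversample_parity <- function(idx, y) {
  tab <- table(y[idx])
  if (length(tab) < 2L) stop("both classes required for oversampling")
  minority <- names(tab)[which.min(tab)]
  need <- max(tab) - min(tab)
  pool <- idx[y[idx] == minority]
  c(idx, sample(pool, need, replace = TRUE))
}

fit_one_elastic_net <- function(x, y, alphas, lambda_grid, cv, nfolds) {
  if (all(apply(x, 2, stats::sd) == 0)) return(NULL)  # no usable predictors
  best <- NULL
  for (a in alphas) {
    nf <- if (cv == "loo") length(y) else nfolds
    fit <- glmnet::cv.glmnet(x, y, family = "binomial", alpha = a,
                             lambda = lambda_grid, nfolds = nf,
                             type.measure = "deviance", standardize = TRUE)
    cvm <- min(fit$cvm)
    if (is.null(best) || cvm < best$cvm) {
      best <- list(fit = fit, alpha = a, cvm = cvm)
    }
  }
  best
}

#' Elastic-net sensitivity classifier over bootstrap simulations
#'
#' Trains a penalized (L1 + L2) logistic regression of the sensitive /
#' insensitive label over `B` simulations. Each simulation bootstraps the
#' rows, oversamples the minority class to exact parity by random
#' duplication, selects the mixing and strength hyperparameters on a grid
#' by cross-validated deviance within the training set, and evaluates AUC
#' on the out-of-bootstrap rows. Features are standardized inside each
#' training fit only.
#'
#' @param features data frame from [assemble_features()] (`row_id` +
#'   numeric columns).
#' @param labels named 0/1 vector (1 = sensitive), names = row ids.
#' @param B simulations (default 100).
#' @param seed RNG seed.
#' @param alphas elastic-net mixing grid (default 0.1, 0.5, 0.9).
#' @param lambda_grid penalty-strength grid (default log-spaced 1e-3..10).
#' @param cv hyperparameter selection: `"oob"` (default, 5-fold inside the
#'   bootstrap) or `"loo"` (leave-one-out; small inputs only).
#' @param nfolds folds for `cv = "oob"`.
#' @return Object of class `model_report`: `mean_auc`, `aucs`,
#'   `coefficients` (feature x simulation matrix), `coef_mean`, `coef_sd`,
#'   `mean_prob` (named mean predicted probability per row), `B`.
#' @export
train_elastic_net <- function(features, labels, B = 100, seed = 1L,
                              alphas = c(0.1, 0.5, 0.9),
                              lambda_grid = 10^seq(1, -3, length.out = 25),
                              cv = c("oob", "loo"), nfolds = 5L) {
  cv <- match.arg(cv)
  x <- as.matrix(features[setdiff(names(features), "row_id")])
  rownames(x) <- features$row_id
  y <- as.numeric(labels[features$row_id])
  if (any(is.na(y))) stop("labels missing for some rows")
  if (length(unique(y)) < 2L) stop("both classes must be present")
  if (min(table(y)) < 3L) stop("minority class too small (< 3)")
  n <- nrow(x)
  with_subseed(seed, "train_elastic_net", {
    aucs <- numeric(B)
    probs <- matrix(NA_real_, n, B)
    coefs <- matrix(NA_real_, ncol(x) + 1L, B,
                    dimnames = list(c("(Intercept)", colnames(x)), NULL))
    for (b in seq_len(B)) {
      repeat {   # a bootstrap draw must contain both classes
        boot <- sample.int(n, n, replace = TRUE)
        if (length(unique(y[boot])) == 2L) break
      }
      oob <- setdiff(seq_len(n), unique(boot))
      train <- oversample_parity(boot, y)
      best <- fit_one_elastic_net(x[train, , drop = FALSE], y[train],
                                  alphas, lambda_grid, cv, nfolds)
      if (is.null(best)) {
        # degenerate (all-constant) features: intercept-only model fitted to
        # the class-balanced training draw
        p0 <- mean(y[train])
        pr <- rep(p0, n)
        coefs[, b] <- c(logit(p0), rep(0, ncol(x)))
      } else {
        pr <- as.numeric(stats::predict(best$fit, newx = x, s = "lambda.min",
                                        type = "response"))
        coefs[, b] <- as.numeric(stats::coef(best$fit, s = "lambda.min"))
      }
      probs[, b] <- pr
      aucs[b] <- if (length(oob)) rank_auc(pr[oob], y[oob]) else NA_real_
    }
    structure(list(mean_auc = mean(aucs, na.rm = TRUE), aucs = aucs,
                   coefficients = coefs,
                   coef_mean = rowMeans(coefs), coef_sd = apply(coefs, 1, stats::sd),
                   mean_prob = stats::setNames(rowMeans(probs), rownames(x)),
                   B = B),
              class = "model_report")
  })
}

#' @export
print.model_report <- function(x, ...) {
  cat(sprintf("model_report: mean AUC %.3f over %d simulations\n",
              x$mean_auc, x$B))
  invisible(x)
}

#' Mean predicted sensitivity from a reduced feature set
#'
#' Re-runs the bootstrap simulation protocol of [train_elastic_net()] using
#' only a reduced feature set (e.g. gene length, G/C content, median intron
#' length, speckle proximity, SF3B4 and SF3A3 occupancy) and returns each
#' row's predicted sensitivity probability averaged over the simulations.
#'
#' @param features full feature data frame.
#' @param labels named 0/1 labels.
#' @param reduced_features character vector of feature columns to keep
#'   (must all exist).
#' @param B simulations (default 100).
#' @param seed RNG seed.
#' @param ... further arguments to [train_elastic_net()].
#' @return Named numeric vector: mean predicted probability per row.
#' @export
predict_reduced <- function(features, labels, reduced_features, B = 100,
                            seed = 1L, ...) {
  missing <- setdiff(reduced_features, names(features))
  if (length(missing)) stop("unseen feature column(s): ",
                            paste(missing, collapse = ", "))
  red <- features[c("row_id", reduced_features)]
  report <- train_elastic_net(red, labels, B = B, seed = seed, ...)
  report$mean_prob
}
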