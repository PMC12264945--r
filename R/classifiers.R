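#' Specification of a contact-pair classifier
#'
#' Five tabular model families plus a small convolutional map-to-map network
#' are supported. Hyperparameters default to the backing libraries' defaults
#' and are recorded verbatim into the trained model's provenance.
#'
#' @param kind One of \code{"logistic"}, \code{"decision_tree"},
#'   \code{"random_forest"}, \code{"mlp"}, \code{"gradient_boosting"},
#'   \code{"cnn"}.
#' @param seed Integer seed used by stochastic kinds.
#' @param ... Hyperparameter overrides passed to the backing fitter.
#' @return A \code{predictor_spec}.
#' @export
predictor_spec <- function(kind = c("logistic", "decision_tree", "random_forest",
                                    "mlp", "gradient_boosting", "cnn"),
                           seed = 1L, ...) {
  kind <- match.arg(kind)
  structure(list(kind = kind, seed = as.integer(seed), hyper = list(...)),
            class = "predictor_spec")
}

#' Train a tabular contact-pair classifier
#'
#' Fits one of the five tabular families on a balanced token-pair table.
#' All fits are deterministic for a fixed seed and fixed input order.
#'
#' @param ds A balanced \code{pair_dataset} (see [balance_dataset()]).
#' @param spec A [predictor_spec()] with \code{kind != "cnn"}.
#' @return An \code{attn_predictor} exposing per-pair contact probabilities
#'   via [predict_pair_prob()].
#' @export
train_tabular <- function(ds, spec) {
  stopifnot(inherits(spec, "predictor_spec"))
  if (spec$kind == "cnn") stop_attn("use train_cnn() for the cnn kind", "attn_config_error")
  if (nrow(ds) == 0L) stop_attn("cannot train on an empty dataset", "attn_training_error")
  if (!isTRUE(attr(ds, "balanced")))
    warn("training on an unbalanced dataset; balance_dataset() is the usual path")
  fnames <- attr(ds, "feature_names")
  X <- as.matrix(as_tibble(ds)[, fnames, drop = FALSE])
  y <- as.integer(ds$label)
  hy <- spec$hyper
  fit <- withr::with_seed(spec$seed, switch(
    spec$kind,
    logistic = {
      df <- data.frame(X, check.names = FALSE); df$.y <- y
      # perfect separation is routine on strongly structure-aware features;
      # the resulting convergence warnings are expected, not actionable
      muffle_glm(do.call(stats::glm, c(list(formula = .y ~ ., data = df,
                                            family = stats::binomial()), hy)))
    },
    decision_tree = {
      df <- data.frame(X, check.names = FALSE); df$.y <- factor(y, levels = c(0, 1))
      do.call(rpart::rpart, c(list(formula = .y ~ ., data = df, method = "class"), hy))
    },
    random_forest = {
      df <- data.frame(X, check.names = FALSE); df$.y <- factor(y, levels = c(0, 1))
      do.call(ranger::ranger, c(list(formula = .y ~ ., data = df,
                                     probability = TRUE, seed = spec$seed,
                                     num.threads = 1L), hy))
    },
    mlp = {
      args <- c(list(x = X, y = y, size = hy$size %||% 16L,
                     decay = hy$decay %||% 1e-4,
                     maxit = hy$maxit %||% 200L,
                     trace = FALSE,
                     MaxNWts = 100000L),
                hy[setdiff(names(hy), c("size", "decay", "maxit"))])
      do.call(nnet::nnet, args)
    },
    gradient_boosting = {
      dtrain <- xgboost::xgb.DMatrix(X, label = y)
      params <- c(list(objective = "binary:logistic", nthread = 1L,
                       seed = spec$seed),
                  hy[setdiff(names(hy), "nrounds")])
      xgboost::xgb.train(params = params, data = dtrain,
                         nrounds = hy$nrounds %||% 100L, verbose = 0L)
    }
  ))
  # drop the spliced call and captured environments so serialized models are
  # byte-stable and do not drag the training frame along; every predictor
  # variable is supplied explicitly at prediction time
  if (!is.null(fit$call)) fit$call <- NULL
  if (spec$kind %in% c("logistic", "decision_tree")) {
    if (!is.null(fit$terms)) attr(fit$terms, ".Environment") <- baseenv()
    if (!is.null(fit$formula)) environment(fit$formula) <- baseenv()
    if (!is.null(fit$model) && !is.null(attr(fit$model, "terms")))
      attr(attr(fit$model, "terms"), ".Environment") <- baseenv()
  }
  structure(list(
    spec = spec, fit = fit, feature_names = fnames,
    provenance = list(n_samples = nrow(ds), balanced = isTRUE(attr(ds, "balanced")),
                      window = attr(ds, "window"), dataset_hash = rlang::hash(ds),
                      hyper = spec$hyper)
  ), class = "attn_predictor")
}

#' @export
print.attn_predictor <- function(x, ...) {
  cat(sprintf("<attn_predictor> kind = %s, features = %d, trained on %d samples\n",
              x$spec$kind, length(x$feature_names), x$provenance$n_samples))
  invisible(x)
}

#' Contact probability for a feature matrix
#'
#' @param model An \code{attn_predictor}.
#' @param X Numeric matrix with columns matching the model's feature names.
#' @return Numeric vector of contact probabilities in \eqn{[0, 1]}.
#' @export
predict_pair_prob <- function(model, X) {
  if (!identical(colnames(X), model$feature_names)) {
    if (is.null(colnames(X)) && ncol(X) == length(model$feature_names)) {
      colnames(X) <- model$feature_names
    } else {
      stop_attn("feature columns do not match the trained model", "attn_feature_error")
    }
  }
  p <- switch(model$spec$kind,
    logistic = {
      df <- data.frame(X, check.names = FALSE)
      muffle_glm(as.numeric(stats::predict(model$fit, newdata = df,
                                           type = "response")))
    },
    decision_tree = {
      df <- data.frame(X, check.names = FALSE)
      as.numeric(stats::predict(model$fit, newdata = df, type = "prob")[, "1"])
    },
    random_forest = {
      df <- data.frame(X, check.names = FALSE)
      as.numeric(stats::predict(model$fit, data = df, num.threads = 1L)$predictions[, "1"])
    },
    mlp = as.numeric(stats::predict(model$fit, X)),
    gradient_boosting = as.numeric(stats::predict(model$fit, xgboost::xgb.DMatrix(X))),
    cnn = stop_attn("cnn models predict whole maps; use predict_contact_map()",
                    "attn_config_error")
  )
  pmin(pmax(p, 0), 1)
}

#' Predict a contact map for one molecule
#'
#' Computes a contact probability for every eligible pair (j - i > window)
#' from the molecule's processed attention features, mirrors it to the lower
#' triangle, forces the exclusion band (and the diagonal) to 0, and
#' thresholds to a binary map.
#'
#' @param model An \code{attn_predictor} (tabular or cnn).
#' @param stack A processed [attention_stack()].
#' @param window Exclusion band half-width.
#' @param threshold Probability threshold for the binary map (default 0.5).
#' @return A \code{predicted_map}: list with \code{n}, \code{prob} (symmetric
#'   N x N), \code{binary} (a [contact_map()]), \code{threshold}.
#' @export
predict_contact_map <- function(model, stack, window, threshold = 0.5) {
  stopifnot(inherits(stack, "attention_stack"))
  if (!stack$processed)
    stop_attn("prediction requires a processed stack", "attn_state_error")
  n <- stack$n
  prob <- matrix(0, n, n)
  if (model$spec$kind == "cnn") {
    prob <- cnn_predict_map(model, stack, window)
  } else {
    if (stack$L * stack$H != length(model$feature_names))
      stop_attn(sprintf("stack has %d features per pair but model expects %d",
                        stack$L * stack$H, length(model$feature_names)),
                "attn_feature_error")
    pr <- eligible_pairs(n, window)
    if (nrow(pr) > 0) {
      X <- matrix(0, nrow(pr), stack$L * stack$H)
      col <- 0L
      for (l in seq_len(stack$L)) for (h in seq_len(stack$H)) {
        col <- col + 1L
        X[, col] <- stack$weights[l, h, , ][cbind(pr$i, pr$j)]
      }
      colnames(X) <- model$feature_names
      p <- predict_pair_prob(model, X)
      prob[cbind(pr$i, pr$j)] <- p
      prob[cbind(pr$j, pr$i)] <- p
    }
  }
  prob[!eligible_mask(n, window)] <- 0
  binary <- contact_map((prob >= threshold) * 1L, window = as.integer(window))
  structure(list(n = n, prob = prob, binary = binary, threshold = threshold,
                 molecule_id = stack$molecule_id),
            class = "predicted_map")
}

#' @export
print.predicted_map <- function(x, ...) {
  cat(sprintf("<predicted_map> %s: n = %d, %d predicted contacts at threshold %.2f\n",
              x$molecule_id, x$n, n_contacts(x$binary), x$threshold))
  invisible(x)
}

#' Save / load a trained predictor
#'
#' The archive stores the spec, the fitted state, feature names, provenance,
#' a format version, and a small probe (features plus the probabilities the
#' model produced at save time). \code{load_model()} replays the probe and
#' refuses to load if predictions have drifted or the file is corrupt.
#'
#' @param model An \code{attn_predictor}.
#' @param path Output path (.rds archive).
#' @export
save_model <- function(model, path) {
  probe <- NULL
  if (model$spec$kind != "cnn") {
    k <- length(model$feature_names)
    X <- matrix(seq(-0.4, 0.6, length.out = 8L * k), 8L, k)
    colnames(X) <- model$feature_names
    probe <- list(X = X, prob = predict_pair_prob(model, X))
  }
  saveRDS(list(format_version = 1L, model = model, probe = probe), path, version = 3L)
  invisible(path)
}

#' @rdname save_model
#' @return \code{load_model()} returns the \code{attn_predictor}.
#' @export
load_model <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e)
    stop_attn(sprintf("cannot read model archive '%s': %s", path, conditionMessage(e)),
              "attn_load_error"))
  if (!is.list(obj) || !identical(obj$format_version, 1L) || !inherits(obj$model, "attn_predictor"))
    stop_attn("not a recognized model archive (format version mismatch)", "attn_load_error")
  if (!is.null(obj$probe)) {
    got <- predict_pair_prob(obj$model, obj$probe$X)
    if (max(abs(got - obj$probe$prob)) > 1e-8)
      stop_attn("probe predictions drifted after load", "attn_load_error")
  }
  obj$model
}

#' Tidy a fitted contact-pair predictor
#'
#' For logistic models, returns one row per attention head with its
#' coefficient: heads with large coefficient magnitudes are the ones the
#' probe relies on, mirroring per-head agreement analyses. Other kinds return
#' their native importance where available.
#'
#' @param x An \code{attn_predictor}.
#' @param ... Unused.
#' @return A tibble with columns \code{term} (layerX_headY),
#'   \code{estimate}, and for logistic fits \code{std.error}.
#' @method tidy attn_predictor
#' @export
tidy.attn_predictor <- function(x, ...) {
  switch(x$spec$kind,
    logistic = {
      cf <- summary(x$fit)$coefficients
      tibble(term = rownames(cf), estimate = cf[, 1], std.error = cf[, 2]) |>
        dplyr::filter(.data$term != "(Intercept)") |>
        dplyr::mutate(term = gsub("`", "", .data$term))
    },
    random_forest = {
      imp <- x$fit$variable.importance
      if (is.null(imp)) tibble(term = x$feature_names, estimate = NA_real_)
      else tibble(term = names(imp), estimate = unname(imp))
    },
    gradient_boosting = {
      imp <- xgboost::xgb.importance(model = x$fit)
      tibble(term = imp$Feature, estimate = imp$Gain)
    },
    tibble(term = x$feature_names, estimate = NA_real_)
  )
}

#' @rdname tidy.attn_predictor
#' @method glance attn_predictor
#' @export
glance.attn_predictor <- function(x, ...) {
  tibble(kind = x$spec$kind, n_features = length(x$feature_names),
         n_samples = x$provenance$n_samples, seed = x$spec$seed)
}
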