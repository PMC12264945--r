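confusion_counts <- function(truth, pred) {
  c(tp = sum(truth == 1 & pred == 1), fn = sum(truth == 1 & pred == 0),
    fp = sum(truth == 0 & pred == 1), tn = sum(truth == 0 & pred == 0))
}

f1_class <- function(tp, fp, fn) {
  den <- 2 * tp + fp + fn
  if (den == 0) 0 else 2 * tp / den  # empty-class F1 defined as 0
}

mcc_from_counts <- function(cc) {
  num <- cc["tp"] * cc["tn"] - cc["fp"] * cc["fn"]
  den <- sqrt(prod(c(cc["tp"] + cc["fp"], cc["tp"] + cc["fn"],
                     cc["tn"] + cc["fp"], cc["tn"] + cc["fn"])))
  if (den == 0) 0 else unname(num / den)  # zero-denominator MCC defined as 0
}

#' Macro-F1 and MCC on flattened binary vectors
#'
#' Macro-F1 is the unweighted mean of the contact-class and
#' non-contact-class F1; MCC is computed from the 2x2 confusion table, with
#' a zero denominator giving 0.
#'
#' @param truth,pred Binary vectors of equal length.
#' @return A list with \code{f1_macro}, \code{mcc}, and the confusion counts.
#' @export
binary_pair_metrics <- function(truth, pred) {
  stopifnot(length(truth) == length(pred))
  cc <- confusion_counts(truth, pred)
  f1_contact <- f1_class(cc["tp"], cc["fp"], cc["fn"])
  f1_background <- f1_class(cc["tn"], cc["fn"], cc["fp"])
  list(f1_macro = unname((f1_contact + f1_background) / 2),
       mcc = mcc_from_counts(cc),
       counts = cc)
}

#' Score one predicted contact map against the truth
#'
#' Both maps are flattened over the eligible upper-triangle pairs
#' (\code{j - i > window}) — the same sample space the classifiers saw — and
#' compared as 1D binary vectors.
#'
#' @param pred A [contact_map()] or \code{predicted_map}.
#' @param truth A [contact_map()].
#' @param window Band half-width; defaults to the truth map's window.
#' @param molecule_id Id recorded in the score row.
#' @return One-row tibble: \code{molecule_id}, \code{f1_macro}, \code{mcc},
#'   \code{n_eligible_pairs}, \code{n_true_contacts}, \code{degenerate}
#'   (TRUE when the truth has no contacts among eligible pairs).
#' @export
score_molecule <- function(pred, truth, window = NULL, molecule_id = NA_character_) {
  if (inherits(pred, "predicted_map")) {
    if (is.na(molecule_id)) molecule_id <- pred$molecule_id
    pred <- pred$binary
  }
  stopifnot(inherits(pred, "contact_map"), inherits(truth, "contact_map"))
  if (pred$n != truth$n)
    stop_attn(sprintf("prediction has n = %d but truth has n = %d", pred$n, truth$n),
              "attn_alignment_error")
  w <- window %||% truth$window
  sel <- eligible_mask(truth$n, w, upper_only = TRUE)
  tv <- truth$matrix[sel]; pv <- pred$matrix[sel]
  m <- binary_pair_metrics(tv, pv)
  tibble(molecule_id = molecule_id, f1_macro = m$f1_macro, mcc = m$mcc,
         n_eligible_pairs = length(tv), n_true_contacts = sum(tv),
         degenerate = sum(tv) == 0L || sum(tv) == length(tv))
}

#' Score a set of predictions
#'
#' Scores every molecule with [score_molecule()] and reports the arithmetic
#' mean of the per-molecule macro-F1 and MCC over the scored molecules.
#' Molecules with no eligible pairs are skipped and listed with a reason.
#'
#' @param preds Named list of predictions ([contact_map()] or
#'   \code{predicted_map}) keyed by molecule id.
#' @param truths Named list of truth [contact_map()]s.
#' @param window Band half-width; defaults to each truth's window.
#' @return An \code{eval_report}: list with \code{scores} (tibble),
#'   \code{mean_f1_macro}, \code{mean_mcc}, \code{skipped} (tibble of id,
#'   reason), \code{params}.
#' @export
score_dataset <- function(preds, truths, window = NULL) {
  ids <- names(truths)
  if (is.null(ids)) stop_attn("truths must be a named list", "attn_config_error")
  missing <- setdiff(ids, names(preds))
  if (length(missing) > 0)
    stop_attn(paste0("missing prediction for: ", paste(missing, collapse = ", ")),
              "attn_alignment_error")
  ids <- sort(ids)
  rows <- list(); skipped <- list()
  for (id in ids) {
    tr <- truths[[id]]
    w <- window %||% tr$window
    if (sum(eligible_mask(tr$n, w, upper_only = TRUE)) == 0L) {
      skipped[[id]] <- tibble(molecule_id = id, reason = "no eligible pairs")
      next
    }
    rows[[id]] <- score_molecule(preds[[id]], tr, window = w, molecule_id = id)
  }
  scores <- dplyr::bind_rows(rows)
  structure(list(
    scores = scores,
    mean_f1_macro = if (nrow(scores)) mean(scores$f1_macro) else NA_real_,
    mean_mcc = if (nrow(scores)) mean(scores$mcc) else NA_real_,
    skipped = dplyr::bind_rows(skipped) %||%
      tibble(molecule_id = character(0), reason = character(0)),
    params = list(window = window)
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %d molecule(s) scored, %d skipped\n",
              nrow(x$scores), nrow(x$skipped)))
  cat(sprintf("  mean macro-F1 = %.4f, mean MCC = %.4f\n",
              x$mean_f1_macro, x$mean_mcc))
  invisible(x)
}

#' @method tidy eval_report
#' @export
tidy.eval_report <- function(x, ...) x$scores

#' @method glance eval_report
#' @export
glance.eval_report <- function(x, ...) {
  tibble(n_scored = nrow(x$scores), n_skipped = nrow(x$skipped),
         mean_f1_macro = x$mean_f1_macro, mean_mcc = x$mean_mcc)
}

#' Sample-level metrics on a held-out pair table
#'
#' Scores classifier probabilities against pair labels after thresholding —
#' the classifier-level view of performance, complementary to the map-level
#' [score_molecule()].
#'
#' @param labels Binary labels.
#' @param prob Predicted contact probabilities.
#' @param threshold Decision threshold (default 0.5).
#' @return Tibble with \code{f1_macro}, \code{mcc}, \code{accuracy},
#'   \code{n}.
#' @export
score_pairs <- function(labels, prob, threshold = 0.5) {
  pred <- as.integer(prob >= threshold)
  m <- binary_pair_metrics(labels, pred)
  tibble(f1_macro = m$f1_macro, mcc = m$mcc,
         accuracy = mean(labels == pred), n = length(labels))
}

#' Benchmark external structure predictions as contact maps
#'
#' Converts each external prediction — a PDB/mmCIF file or a dot-bracket
#' string — into a contact map with the same cutoff and exclusion window as
#' the truth maps, then scores the set. Unparsable predictions are skipped
#' per molecule with a reason, never failing the whole benchmark.
#'
#' @param predictions Named list keyed by molecule id; each element either a
#'   file path (PDB/mmCIF) or a dot-bracket string.
#' @param truths Named list of truth [contact_map()]s.
#' @param cutoff Distance cutoff in Angstrom for 3D predictions.
#' @param window Exclusion band half-width.
#' @param kind Molecule kind for 3D parsing.
#' @return An \code{eval_report}; \code{params} records the conversion
#'   settings.
#' @export
benchmark_external <- function(predictions, truths, cutoff = 9.5, window = 4L,
                               kind = "rna") {
  preds <- list(); skipped <- list()
  for (id in names(truths)) {
    src <- predictions[[id]]
    if (is.null(src)) {
      skipped[[id]] <- tibble(molecule_id = id, reason = "no prediction supplied")
      next
    }
    map <- tryCatch({
      if (file.exists(src)) {
        st <- read_structure(src, kind = kind, id = id)
        apply_exclusion_band(coords_to_contact_map(st, cutoff = cutoff), window)
      } else {
        pr <- dotbracket_to_pairs(src)
        apply_exclusion_band(pairs_to_contact_map(pr, attr(pr, "n")), window)
      }
    }, error = function(e) e)
    if (inherits(map, "error")) {
      skipped[[id]] <- tibble(molecule_id = id, reason = conditionMessage(map))
      next
    }
    if (map$n != truths[[id]]$n) {
      skipped[[id]] <- tibble(molecule_id = id,
                              reason = sprintf("length %d != truth %d", map$n, truths[[id]]$n))
      next
    }
    preds[[id]] <- map
  }
  report <- score_dataset(preds, truths[names(preds)], window = window)
  report$skipped <- dplyr::bind_rows(report$skipped, dplyr::bind_rows(skipped))
  report$params <- list(cutoff = cutoff, window = window, kind = kind)
  report
}

#' Truth-versus-prediction overlay plot
#'
#' Shows the truth contacts in the upper triangle and the predicted contacts
#' in the lower triangle of one map — the standard visual comparison layout.
#'
#' @param truth A [contact_map()].
#' @param pred A [contact_map()] or \code{predicted_map}.
#' @param molecule_id Title annotation.
#' @return A ggplot object.
#' @export
plot_contact_overlay <- function(truth, pred, molecule_id = NULL) {
  if (inherits(pred, "predicted_map")) {
    molecule_id <- molecule_id %||% pred$molecule_id
    pred <- pred$binary
  }
  n <- truth$n
  up <- which(truth$matrix == 1L & upper.tri(truth$matrix), arr.ind = TRUE)
  lo <- which(pred$matrix == 1L & upper.tri(pred$matrix), arr.ind = TRUE)
  df <- dplyr::bind_rows(
    tibble(i = up[, 1], j = up[, 2], which = "truth"),
    tibble(i = lo[, 2], j = lo[, 1], which = "prediction")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$j, y = .data$i, colour = .data$which)) +
    ggplot2::geom_point(shape = 15, size = 1) +
    ggplot2::scale_y_reverse(limits = c(n, 1)) +
    ggplot2::scale_x_continuous(limits = c(1, n)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = molecule_id %||% "contact map",
                  subtitle = "truth above the diagonal, prediction below",
                  x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
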