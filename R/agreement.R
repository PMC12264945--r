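#' Per-head agreement between attention and structure
#'
#' For every (layer, head) of the grid, computes the fraction of attention
#' mass that falls on true contact pairs, pooled over a set of molecules:
#'
#' \deqn{p(f) = \frac{\sum_x \sum_{(i,j)} f(i,j)\, \ell(a_{ij})}
#'                   {\sum_x \sum_{(i,j)} \ell(a_{ij})}}
#'
#' where \eqn{f(i,j)} is 1 for contacts, and \eqn{\ell(a) = a\,[a > \theta]}
#' when a confidence threshold \eqn{\theta} is set (0.3 by convention), or
#' \eqn{\ell(a) = a} in the threshold-free variant (\code{theta = NULL}). A
#' score near 1 marks a structurally aware head; on uninformative attention
#' the score approaches the contact density of the eligible pair set.
#'
#' @param stacks List of [attention_stack()]s (raw by default; set
#'   \code{use_processed = TRUE} to score symmetrized/APC maps).
#' @param maps Named list of [contact_map()]s aligned to the stacks by
#'   molecule id (or by position when unnamed).
#' @param theta Attention threshold in \eqn{[0, 1)}, or \code{NULL} for the
#'   threshold-free variant.
#' @param mask_policy \code{"band_excluded"} drops pairs with
#'   \code{|i - j| <= window} from numerator and denominator (matching the
#'   contact maps' exclusion band); \code{"all"} sums over every (i, j)
#'   including the diagonal.
#' @param use_processed Allow scoring processed stacks.
#' @return A \code{head_score_grid}: tibble with columns \code{layer},
#'   \code{head}, \code{score}, \code{flagged} (TRUE when the head's
#'   denominator was 0 and the score was defined as 0), carrying
#'   \code{theta}, \code{mask_policy} and \code{n_molecules} attributes.
#' @export
agreement_scores <- function(stacks, maps, theta = 0.3,
                             mask_policy = c("band_excluded", "all"),
                             use_processed = FALSE) {
  mask_policy <- match.arg(mask_policy)
  if (!is.null(theta) && (theta < 0 || theta >= 1))
    stop_attn("theta must be in [0, 1) or NULL", "attn_config_error")
  stopifnot(length(stacks) >= 1L, length(stacks) == length(maps))
  ids <- vapply(stacks, `[[`, character(1), "molecule_id")
  if (!is.null(names(maps))) {
    missing <- setdiff(ids, names(maps))
    if (length(missing) > 0)
      stop_attn(paste0("no contact map for: ", paste(missing, collapse = ", ")),
                "attn_alignment_error")
    maps <- maps[ids]
  }
  L <- stacks[[1]]$L; H <- stacks[[1]]$H
  num <- matrix(0, L, H); den <- matrix(0, L, H)
  for (k in seq_along(stacks)) {
    st <- stacks[[k]]; mp <- maps[[k]]
    if (st$processed && !use_processed)
      stop_attn("stack is processed; agreement is defined on raw attention (set use_processed = TRUE to override)",
                "attn_state_error")
    if (st$L != L || st$H != H) stop_attn("stacks disagree on (L, H)", "attn_shape_error")
    if (st$n != mp$n)
      stop_attn(sprintf("stack '%s' has n = %d but its map has n = %d",
                        st$molecule_id, st$n, mp$n), "attn_alignment_error")
    elig <- if (mask_policy == "all") matrix(TRUE, st$n, st$n)
            else eligible_mask(st$n, mp$window)
    fm <- mp$matrix == 1L & elig
    for (l in seq_len(L)) for (h in seq_len(H)) {
      a <- st$weights[l, h, , ]
      if (!is.null(theta)) a <- a * (a > theta)
      num[l, h] <- num[l, h] + sum(a[fm])
      den[l, h] <- den[l, h] + sum(a[elig])
    }
  }
  flagged <- den == 0
  if (any(flagged))
    warn(sprintf("%d head(s) received no eligible attention mass; their score is defined as 0",
                 sum(flagged)))
  score <- ifelse(flagged, 0, num / pmax(den, .Machine$double.xmin))
  grid <- tidyr::expand_grid(layer = seq_len(L), head = seq_len(H)) |>
    dplyr::mutate(score = score[cbind(.data$layer, .data$head)],
                  flagged = flagged[cbind(.data$layer, .data$head)])
  structure(grid, class = c("head_score_grid", class(grid)),
            theta = theta, mask_policy = mask_policy,
            n_molecules = length(stacks))
}

#' @export
print.head_score_grid <- function(x, ...) {
  th <- attr(x, "theta")
  cat(sprintf("<head_score_grid> %d layers x %d heads over %d molecule(s); theta = %s, mask = %s\n",
              max(x$layer), max(x$head), attr(x, "n_molecules"),
              if (is.null(th)) "none" else format(th), attr(x, "mask_policy")))
  NextMethod()
}

#' Rank attention heads by agreement score
#'
#' @param grid A \code{head_score_grid}.
#' @param k Number of heads to return (default: all).
#' @return Tibble of \code{layer}, \code{head}, \code{score} sorted by
#'   descending score, ties broken by ascending (layer, head).
#' @export
rank_heads <- function(grid, k = nrow(grid)) {
  stopifnot(k >= 1, k <= nrow(grid))
  grid |>
    as_tibble() |>
    dplyr::arrange(dplyr::desc(.data$score), .data$layer, .data$head) |>
    dplyr::select("layer", "head", "score") |>
    utils::head(k)
}

#' Best-head summary of a score grid
#'
#' The maximum agreement score over all heads: a one-number summary of how
#' much structure the most structurally aware head has captured.
#'
#' @param grid A \code{head_score_grid}.
#' @return A one-row tibble with \code{layer}, \code{head}, \code{score}.
#' @export
best_head <- function(grid) rank_heads(grid, 1L)

#' Write / read head-score grids as TSV (layer, head, score)
#' @param grid A \code{head_score_grid}.
#' @param path Output path.
#' @export
write_head_scores <- function(grid, path) {
  readr::write_tsv(as_tibble(grid)[, c("layer", "head", "score")], path)
  invisible(path)
}

#' @rdname write_head_scores
#' @export
read_head_scores <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Heatmap of per-head agreement scores
#'
#' Layers on the y axis, heads on the x axis, fill mapped to the agreement
#' score — the standard layer-by-head probing heatmap.
#'
#' @param object A \code{head_score_grid}.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot head_score_grid
#' @export
autoplot.head_score_grid <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$head, y = .data$layer, fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = "p(f)") +
    ggplot2::scale_y_reverse(breaks = unique(object$layer)) +
    ggplot2::scale_x_continuous(breaks = unique(object$head)) +
    ggplot2::labs(x = "head", y = "layer",
                  title = "Attention-structure agreement by head") +
    ggplot2::theme_minimal()
}
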