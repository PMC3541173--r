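# broom-style tidiers and ggplot2 autoplot methods for the result types.

#' @export
tidy.profile_hmm <- function(x, ...) {
  emis <- as_tibble(x$match_emissions)
  bind_cols(tibble(state = seq_len(x$match_count)), emis,
            as_tibble(x$transitions))
}

#' @export
glance.profile_hmm <- function(x, ...) {
  tibble(model_id = x$model_id, model_class = x$model_class,
         match_count = x$match_count,
         inclusion_cutoff = x$inclusion_cutoff,
         unknown_floor = x$unknown_floor)
}

#' @export
tidy.sdr_inventory <- function(x, ...) {
  bind_rows(x$main, x$ambiguous, x$negative)
}

#' @export
glance.sdr_inventory <- function(x, ...) {
  tibble(n_main = nrow(x$main), n_ambiguous = nrow(x$ambiguous),
         n_negative = nrow(x$negative),
         n_families = dplyr::n_distinct(x$main$family_id[
           !is.na(x$main$family_id)]),
         n_orphan_clusters = if (is.null(x$orphan_clusters)) 0L else
           nrow(x$orphan_clusters$clusters))
}

#' @export
tidy.distribution_matrix <- function(x, ...) {
  as_tibble(x$counts, rownames = "family_id") |>
    tidyr::pivot_longer(-"family_id", names_to = "genome",
                        values_to = "n") |>
    mutate(tier = unname(x$tiers[.data$genome]))
}

#' @export
tidy.sdr_pca <- function(x, ...) x$scores

#' @export
glance.sdr_pca <- function(x, ...) {
  tibble(pc1_variance_pct = x$variance_pct[1],
         pc2_variance_pct = if (length(x$variance_pct) > 1)
           x$variance_pct[2] else NA_real_,
         n_axes = length(x$variance_pct),
         centered = isTRUE(x$centering$center),
         scaled = isTRUE(x$centering$scale))
}

#' @export
tidy.distance_matrix <- function(x, ...) {
  as_tibble(x$d, rownames = "id_a") |>
    tidyr::pivot_longer(-"id_a", names_to = "id_b", values_to = "distance") |>
    filter(.data$id_a < .data$id_b) |>
    mutate(kind = x$kind)
}

#' Heat map of a family-by-genome distribution matrix
#'
#' Blue-to-red count gradient with white squares marking absent families,
#' genomes ordered by taxon tier.
#'
#' @param object A `distribution_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.distribution_matrix <- function(object, ...) {
  df <- tidy(object)
  tier_order <- c("alga", "bryophyte", "lycophyte", "angiosperm")
  df$genome <- factor(df$genome, levels = unique(
    names(sort(setNames(match(object$tiers, tier_order),
                        names(object$tiers))))))
  df$count_na <- ifelse(df$n == 0, NA_real_, df$n)
  ggplot2::ggplot(df, ggplot2::aes(.data$genome, .data$family_id,
                                   fill = .data$count_na)) +
    ggplot2::geom_tile(color = "grey80") +
    ggplot2::scale_fill_gradient(low = "#2166ac", high = "#b2182b",
                                 na.value = "white", name = "members") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal(base_size = 9)
}

#' Scatter plot of PCA family scores with genome loading vectors
#'
#' @param object An `sdr_pca`.
#' @param loading_scale Multiplier applied to the loading vectors for
#'   display.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sdr_pca <- function(object, loading_scale = NULL, ...) {
  sc <- object$scores
  lo <- object$loadings
  if (is.null(loading_scale)) {
    loading_scale <- 0.8 * max(abs(c(sc$PC1, sc$PC2))) /
      max(abs(c(lo$PC1, lo$PC2)))
  }
  ggplot2::ggplot(sc, ggplot2::aes(.data$PC1, .data$PC2)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_segment(
      data = lo,
      ggplot2::aes(x = 0, y = 0, xend = .data$PC1 * loading_scale,
                   yend = .data$PC2 * loading_scale),
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
      color = "#b2182b"
    ) +
    ggplot2::geom_text(
      data = lo,
      ggplot2::aes(x = .data$PC1 * loading_scale * 1.08,
                   y = .data$PC2 * loading_scale * 1.08,
                   label = .data$genome),
      color = "#b2182b", size = 3
    ) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", object$variance_pct[1]),
      y = sprintf("PC2 (%.1f%%)", object$variance_pct[2])
    ) +
    ggplot2::theme_minimal(base_size = 10)
}
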