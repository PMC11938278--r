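# broom-style tidiers and ggplot2 autoplot methods for the fitted models
# and evaluation reports.

#' @describeIn new_site_model tidy(): one row per parameter with its layer
#'   and role.
#' @param x a fitted or untrained model object.
#' @param ... unused.
#' @export
tidy.hydrasite_site_model <- function(x, ...) {
  classes <- c("backbone_polar", "sidechain_polar", "apolar", "water")
  layer_rows <- purrr::imap(x$params$layers, function(lp, l) {
    tibble::tibble(
      layer = l,
      term = c(paste0("attention_", rep(classes, each = nrow(lp$a)), "_rbf",
                      seq_len(nrow(lp$a))),
               paste0("message_", rep(classes, each = nrow(lp$b)), "_rbf",
                      seq_len(nrow(lp$b)))),
      estimate = c(lp$a, lp$b)
    )
  })
  head_rows <- tibble::tibble(
    layer = NA_integer_,
    term = c("head_intercept", paste0("head_rbf", seq_along(x$params$head$cvec))),
    estimate = c(x$params$head$c0, x$params$head$cvec)
  )
  dplyr::bind_rows(c(layer_rows, list(head_rows)))
}

#' @describeIn new_site_model glance(): one-row training summary.
#' @export
glance.hydrasite_site_model <- function(x, ...) {
  tibble::tibble(
    n_layers = x$config$n_layers,
    n_params = length(flatten_site_params(x$params)),
    trained = x$trained,
    epochs = nrow(x$history),
    final_loss = if (nrow(x$history)) tail(x$history$loss, 1) else NA_real_
  )
}

#' @describeIn new_thermo_model tidy(): one row per parameter block with
#'   dimensions and norms.
#' @param x a fitted or untrained model object.
#' @param ... unused.
#' @export
tidy.hydrasite_thermo_model <- function(x, ...) {
  blocks <- purrr::imap(x$params$layers, function(lp, l) {
    tibble::tibble(
      layer = l,
      term = c("attention", "self_weight", "neighbor_weight", "bias"),
      n_values = c(length(lp$a), length(lp$W0), length(lp$W1), length(lp$b)),
      norm = c(sqrt(sum(lp$a^2)), sqrt(sum(lp$W0^2)),
               sqrt(sum(lp$W1^2)), sqrt(sum(lp$b^2)))
    )
  })
  hp <- x$params$head
  head_rows <- tibble::tibble(
    layer = NA_integer_,
    term = c("head_hidden", "head_hidden_bias", "head_out", "head_out_bias"),
    n_values = c(length(hp$W2), length(hp$b2), length(hp$W3), length(hp$b3)),
    norm = c(sqrt(sum(hp$W2^2)), sqrt(sum(hp$b2^2)),
             sqrt(sum(hp$W3^2)), sqrt(sum(hp$b3^2)))
  )
  dplyr::bind_rows(c(blocks, list(head_rows)))
}

#' @describeIn new_thermo_model glance(): one-row training summary.
#' @export
glance.hydrasite_thermo_model <- function(x, ...) {
  tibble::tibble(
    n_layers = x$config$n_layers,
    hidden = x$config$hidden,
    n_params = length(flatten_site_params(x$params)),
    trained = x$trained,
    epochs = nrow(x$history),
    final_loss = if (nrow(x$history)) tail(x$history$loss, 1) else NA_real_
  )
}

#' @describeIn evaluate_sites tidy(): the GTRR/PHR rate table in long form.
#' @param x an evaluation report.
#' @param ... unused.
#' @export
tidy.hydrasite_eval <- function(x, ...) {
  tidyr::pivot_longer(x$rates, c("gtrr", "phr"),
                      names_to = "metric", values_to = "value")
}

#' @describeIn evaluate_sites autoplot(): GTRR and PHR versus cutoff.
#' @param object an evaluation report.
#' @export
autoplot.hydrasite_eval <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cutoff, y = .data$value,
                                   colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "distance cutoff (Å)", y = "rate",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn new_site_model autoplot(): the training loss curve.
#' @param object a fitted model.
#' @export
autoplot.hydrasite_site_model <- function(object, ...) {
  ggplot2::ggplot(object$history,
                  ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "training loss") +
    ggplot2::theme_minimal()
}

#' @describeIn new_thermo_model autoplot(): the training loss curve.
#' @param object a fitted model.
#' @export
autoplot.hydrasite_thermo_model <- function(object, ...) {
  ggplot2::ggplot(object$history,
                  ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "training loss") +
    ggplot2::theme_minimal()
}

#' Plot structure and hydration sites (2D projection)
#'
#' Scatter of protein heavy atoms and site centers projected on the x--y
#' plane; sites are colored by `dG` when available, otherwise by weight.
#'
#' @param structure atom tibble.
#' @param sites site tibble.
#' @return A ggplot object.
#' @export
plot_sites <- function(structure, sites) {
  p <- ggplot2::ggplot() +
    ggplot2::geom_point(
      data = structure,
      ggplot2::aes(x = .data$x, y = .data$y), colour = "grey60", size = 1
    ) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (Å)", y = "y (Å)") +
    ggplot2::theme_minimal()
  colour_col <- if ("dG" %in% names(sites)) "dG" else if ("weight" %in% names(sites)) "weight" else NULL
  if (is.null(colour_col)) {
    p + ggplot2::geom_point(data = sites,
                            ggplot2::aes(x = .data$x, y = .data$y),
                            colour = "steelblue", size = 2)
  } else {
    p + ggplot2::geom_point(
      data = sites,
      ggplot2::aes(x = .data$x, y = .data$y, colour = .data[[colour_col]]),
      size = 2
    )
  }
}
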