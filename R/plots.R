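#' Plot a simulated trial
#'
#' Diagnostic plots of one trial: recorded firing-rate traces (one facet per
#' session, members of each context's receptive field coloured), the final
#' recurrent weight matrix, or per-session excitability profiles.
#'
#' @param object An `engram_trial`.
#' @param type `"rates"`, `"weights"` or `"excitability"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.engram_trial <- function(object, type = c("rates", "weights",
                                                   "excitability"), ...) {
  type <- match.arg(type)
  p <- object$params
  if (type == "rates") {
    if (!length(object$traces))
      stop("no traces recorded; rerun with record = \"recall\" or \"all\"",
           call. = FALSE)
    df <- purrr::imap_dfr(object$traces, function(tr, lab) {
      long <- tidyr::pivot_longer(
        tibble::as_tibble(tr$rates, .name_repair = ~ as.character(seq_along(.))),
        dplyr::everything(), names_to = "neuron", values_to = "rate")
      long$time <- rep(tr$times, each = ncol(tr$rates)) / 1000
      long$session <- lab
      long$neuron <- as.integer(long$neuron)
      long
    })
    df$rf <- dplyr::case_when(df$neuron <= 15 ~ "RF 1",
                              df$neuron <= 30 ~ "RF 2",
                              df$neuron <= 45 ~ "RF 3",
                              TRUE ~ "no RF")
    ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$rate,
                                     group = .data$neuron,
                                     colour = .data$rf)) +
      ggplot2::geom_line(linewidth = 0.3, alpha = 0.8) +
      ggplot2::geom_hline(yintercept = p$theta_active, linetype = "dashed") +
      ggplot2::facet_wrap(~ session, scales = "free_x") +
      ggplot2::labs(x = "time (s)", y = "rate (Hz)", colour = NULL) +
      ggplot2::theme_minimal()
  } else if (type == "weights") {
    W <- object$weights[[length(object$weights)]]
    df <- tidyr::expand_grid(post = seq_len(nrow(W)), pre = seq_len(ncol(W)))
    df$w <- as.vector(W)[(df$pre - 1L) * nrow(W) + df$post]
    ggplot2::ggplot(df, ggplot2::aes(.data$pre, .data$post, fill = .data$w)) +
      ggplot2::geom_raster() +
      ggplot2::scale_y_reverse() +
      ggplot2::scale_fill_viridis_c(limits = c(p$w_min, p$w_max)) +
      ggplot2::labs(x = "presynaptic neuron", y = "postsynaptic neuron",
                    fill = "W") +
      ggplot2::coord_fixed() +
      ggplot2::theme_minimal()
  } else {
    df <- purrr::imap_dfr(object$excitability, function(e, lab)
      tibble::tibble(session = lab, neuron = seq_along(e), eps = e))
    df$session <- factor(df$session, levels = names(object$excitability))
    ggplot2::ggplot(df, ggplot2::aes(.data$neuron, .data$eps)) +
      ggplot2::geom_col(width = 1) +
      ggplot2::facet_wrap(~ session) +
      ggplot2::labs(x = "neuron", y = "excitability (a.u.)") +
      ggplot2::theme_minimal()
  }
}

#' Plot per-condition aggregates of an experiment
#'
#' Mean and standard error of a per-trial metric by condition and recall.
#'
#' @param object An `engram_experiment`.
#' @param metric `"overlap"`, `"strength"` or `"size"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.engram_experiment <- function(object,
                                       metric = c("overlap", "strength",
                                                  "size"), ...) {
  metric <- match.arg(metric)
  agg <- glance(object)
  mcol <- paste0("mean_", metric)
  scol <- paste0("sem_", metric)
  if (!mcol %in% names(agg)) mcol <- "mean_size"
  agg <- agg[!is.na(agg[[mcol]]), ]
  ggplot2::ggplot(agg, ggplot2::aes(.data$condition, .data[[mcol]],
                                    fill = .data$label)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.9)) +
    (if (scol %in% names(agg))
      ggplot2::geom_errorbar(
        ggplot2::aes(ymin = .data[[mcol]] - .data[[scol]],
                     ymax = .data[[mcol]] + .data[[scol]]),
        position = ggplot2::position_dodge(0.9), width = 0.2)
     else NULL) +
    ggplot2::labs(x = NULL, y = metric, fill = NULL,
                  title = object$name) +
    ggplot2::theme_minimal()
}
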