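# Tabular outputs, figures and run logging.

#' Write ensemble outputs as tidy CSV
#'
#' `write_ensemble_csv()` writes the per-year summary (year, variable,
#' mean, lo95, hi95, n_reps); `write_records_csv()` writes the raw
#' per-replicate trajectories.
#'
#' @param ensemble An `ev_ensemble`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ensemble_csv <- function(ensemble, path) {
  utils::write.csv(ensemble$summary, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ensemble_csv
#' @export
write_records_csv <- function(ensemble, path) {
  utils::write.csv(ensemble$records, path, row.names = FALSE)
  invisible(path)
}

#' Write a driver series as tidy CSV
#'
#' @param drivers A tibble from [driver_series()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_driver_csv <- function(drivers, path) {
  utils::write.csv(
    drivers[c("year", "month", "rabbit_kg", "griffon_index")],
    path, row.names = FALSE
  )
  invisible(path)
}

#' Structured run log
#'
#' Appends one log line with an ISO-8601 timestamp, the run seed and a hash
#' of the parameter set, so a run directory is self-describing.
#'
#' @param path Log file path.
#' @param seed Run seed.
#' @param params The `ev_params` used.
#' @param note Free-text note.
#' @return `path`, invisibly.
#' @export
write_run_log <- function(path, seed, params, note = "") {
  line <- sprintf("%s seed=%s params=%s %s",
                  format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                  seed, rlang::hash(unclass(params)), note)
  cat(line, "\n", file = path, append = TRUE)
  invisible(path)
}

#' Yearly consumption shares
#'
#' Per-year shares of the consumed rabbit-carcass biomass taken by each
#' species (ensemble means; shares sum to 1 in every year with non-zero
#' consumption).
#'
#' @param ensemble An `ev_ensemble`.
#' @return A tibble: `year`, `ev_share`, `gv_share`.
#' @export
consumption_shares <- function(ensemble) {
  ensemble$summary |>
    dplyr::filter(.data$variable %in% c("rabbit_kg_ev", "rabbit_kg_gv")) |>
    dplyr::select("year", "variable", "mean") |>
    tidyr::pivot_wider(names_from = "variable", values_from = "mean") |>
    dplyr::filter(!is.na(.data$rabbit_kg_ev),
                  .data$rabbit_kg_ev + .data$rabbit_kg_gv > 0) |>
    dplyr::transmute(
      year = .data$year,
      ev_share = .data$rabbit_kg_ev /
        (.data$rabbit_kg_ev + .data$rabbit_kg_gv),
      gv_share = .data$rabbit_kg_gv /
        (.data$rabbit_kg_ev + .data$rabbit_kg_gv)
    )
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Trajectory fan plot for an ensemble
#'
#' Ensemble mean with the percentile 95% band for one census variable.
#' With a single replicate the band collapses onto the line.
#'
#' @param object An `ev_ensemble`.
#' @param variable Census variable to plot (default `"pairs"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.ev_ensemble <- function(object, variable = "pairs", ...) {
  dat <- object$summary |> dplyr::filter(.data$variable == !!variable)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$year, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo95, ymax = .data$hi95),
                         fill = "firebrick", alpha = 0.25) +
    ggplot2::geom_line(colour = "darkgreen", linewidth = 0.8) +
    ggplot2::labs(x = "year", y = variable,
                  title = paste0("Ensemble mean and 95% interval (",
                                 object$n_reps, " replicates)")) +
    ggplot2::theme_minimal()
}

#' Stacked consumption-share plot
#'
#' @param ensemble An `ev_ensemble`.
#' @return A ggplot object (stacked yearly shares; the two species sum to
#'   100% every year).
#' @export
plot_consumption_shares <- function(ensemble) {
  consumption_shares(ensemble) |>
    tidyr::pivot_longer(c("ev_share", "gv_share"),
                        names_to = "species", values_to = "share") |>
    dplyr::mutate(species = dplyr::recode(.data$species,
                                          ev_share = "Egyptian vulture",
                                          gv_share = "Griffon vulture")) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$year, y = .data$share,
                                 fill = .data$species)) +
    ggplot2::geom_area() +
    ggplot2::scale_fill_manual(values = c("Egyptian vulture" = "firebrick",
                                          "Griffon vulture" = "darkgreen")) +
    ggplot2::labs(x = "year", y = "share of consumed rabbit carrion") +
    ggplot2::theme_minimal()
}

#' Response-surface contour plot
#'
#' Filled-contour rendering of a fitted quadratic surface over the coded
#' factor square (the first two coded factors; others held at 0).
#'
#' @param object An `ev_surface`.
#' @param n Grid resolution per axis.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.ev_surface <- function(object, n = 41, ...) {
  f1 <- object$factors[1]
  f2 <- object$factors[2]
  grid <- tidyr::expand_grid(
    a = seq(-1, 1, length.out = n),
    b = seq(-1, 1, length.out = n)
  )
  newdata <- tibble::as_tibble(
    stats::setNames(list(grid$a, grid$b), c(f1, f2))
  )
  for (f in setdiff(object$factors, c(f1, f2))) newdata[[f]] <- 0
  grid$z <- predict(object, newdata)
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$a, y = .data$b,
                                     z = .data$z)) +
    ggplot2::geom_contour_filled() +
    ggplot2::labs(x = paste(f1, "(coded)"), y = paste(f2, "(coded)"),
                  fill = object$response) +
    ggplot2::theme_minimal()
}
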