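#' Read a bee-flower interaction table
#'
#' Reads a CSV with one row per captured bee and the columns
#' `bee_species`, `sociality` (`"solitary"`/`"eusocial"`), `plant_species`
#' and `symmetry` (`"radial"`/`"bilateral"`), plus the optional trait and
#' design columns `bee_genus`, `proboscis_mm`, `corolla_mm`, `round`,
#' `plot`. Sociality and symmetry are normalized to lower case; rows whose
#' sociality is not binary (e.g. intermediate sociality levels) or whose
#' symmetry is unrecognized are dropped with a message reporting the count.
#'
#' @param path Path to the CSV file.
#' @return A tibble of interaction records.
#' @export
read_interactions <- function(path) {
  mandatory <- c("bee_species", "sociality", "plant_species", "symmetry")
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing_cols <- setdiff(mandatory, names(tbl))
  if (length(missing_cols)) {
    stop("interaction table is missing mandatory columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(tbl) == 0) return(tbl)
  tbl <- tbl |>
    dplyr::mutate(
      sociality = tolower(trimws(as.character(.data$sociality))),
      symmetry = tolower(trimws(as.character(.data$symmetry)))
    )
  keep <- tbl$sociality %in% c("solitary", "eusocial") &
    tbl$symmetry %in% c("radial", "bilateral")
  if (any(!keep)) {
    message("dropped ", sum(!keep),
            " record(s) with non-binary sociality or unrecognized symmetry")
    tbl <- tbl[keep, ]
  }
  if ("proboscis_mm" %in% names(tbl) &&
      any(tbl$proboscis_mm <= 0, na.rm = TRUE)) {
    stop("`proboscis_mm` must be positive where present", call. = FALSE)
  }
  if ("corolla_mm" %in% names(tbl) &&
      any(tbl$corolla_mm < 0, na.rm = TRUE)) {
    stop("`corolla_mm` must be non-negative where present", call. = FALSE)
  }
  tbl
}

#' Code flower complexity proxies
#'
#' Adds two logical columns: `is_bilateral` (bilateral symmetry constrains
#' the landing angle and is the binary complexity proxy) and `is_deep`
#' (corolla tube strictly longer than `deep_threshold` mm; a tube of
#' exactly the threshold codes as shallow). The 3 mm default is the median
#' tube length in the field dataset this schema mirrors.
#'
#' @param tbl An interaction tibble (see [read_interactions()]).
#' @param deep_threshold Corolla depth cut-off in mm.
#' @return The tibble with `is_bilateral` and `is_deep` added.
#' @export
code_complexity <- function(tbl, deep_threshold = 3) {
  tbl |>
    dplyr::mutate(
      is_bilateral = .data$symmetry == "bilateral",
      is_deep = if ("corolla_mm" %in% names(tbl)) {
        .data$corolla_mm > deep_threshold
      } else {
        NA
      }
    )
}

#' Visit counts by flower class
#'
#' @param tbl An interaction tibble.
#' @param by `"symmetry"` (radial/bilateral) or `"depth"` (deep/shallow,
#'   coded via [code_complexity()]; rows with missing corolla are
#'   excluded).
#' @param deep_threshold Passed to [code_complexity()].
#' @return A tibble with columns `class` and `n`; the classes partition
#'   the (usable) visits exactly.
#' @export
complexity_counts <- function(tbl, by = c("symmetry", "depth"),
                              deep_threshold = 3) {
  by <- match.arg(by)
  tbl <- code_complexity(tbl, deep_threshold)
  if (by == "symmetry") {
    cls <- factor(ifelse(tbl$is_bilateral, "bilateral", "radial"),
                  levels = c("radial", "bilateral"))
  } else {
    tbl <- tbl[!is.na(tbl$is_deep), ]
    cls <- factor(ifelse(tbl$is_deep, "deep", "shallow"),
                  levels = c("shallow", "deep"))
  }
  tibble::tibble(class = factor(levels(cls), levels = levels(cls))) |>
    dplyr::left_join(
      tibble::tibble(class = cls) |> dplyr::count(.data$class),
      by = "class"
    ) |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L))
}

#' Per-species visit proportions to complex flowers, by sociality
#'
#' For each bee species, the proportion of its visits that target the
#' focal flower class (bilateral, or deep-tubed); then, per sociality
#' group, the *unweighted* mean of those species-level proportions with
#' its standard error `sd / sqrt(n_species)`. Species-level averaging
#' prevents a few very abundant species from dominating the group
#' summary. Species contributing no usable visit are excluded; a group
#' with a single species reports `NA` standard error.
#'
#' @param tbl An interaction tibble.
#' @param trait `"bilateral"` or `"deep"`.
#' @param deep_threshold Passed to [code_complexity()].
#' @param summarise If `FALSE`, return the species-level table instead of
#'   the group summary.
#' @param sd_type `"sample"` (divisor `n - 1`, default) or `"population"`
#'   (divisor `n`) for the standard deviation across species.
#' @return A tibble: per sociality group, `n_species`, `mean_proportion`,
#'   `se` (or the species-level proportions when `summarise = FALSE`).
#' @export
per_species_proportions <- function(tbl, trait = c("bilateral", "deep"),
                                    deep_threshold = 3, summarise = TRUE,
                                    sd_type = c("sample", "population")) {
  trait <- match.arg(trait)
  sd_type <- match.arg(sd_type)
  tbl <- code_complexity(tbl, deep_threshold)
  flag <- if (trait == "bilateral") tbl$is_bilateral else tbl$is_deep
  tbl <- tbl[!is.na(flag), ]
  flag <- flag[!is.na(flag)]
  species <- tbl |>
    dplyr::mutate(.flag = flag) |>
    dplyr::group_by(.data$bee_species, .data$sociality) |>
    dplyr::summarise(
      n_visits = dplyr::n(),
      n_trait = sum(.data$.flag),
      proportion = .data$n_trait / .data$n_visits,
      .groups = "drop"
    )
  if (!summarise) return(species)
  species |>
    dplyr::group_by(.data$sociality) |>
    dplyr::summarise(
      n_species = dplyr::n(),
      mean_proportion = mean(.data$proportion),
      se = group_se(.data$proportion, sd_type),
      .groups = "drop"
    )
}

group_se <- function(x, sd_type = "sample") {
  n <- length(x)
  if (n < 2) return(NA_real_)
  s <- stats::sd(x)
  if (sd_type == "population") s <- s * sqrt((n - 1) / n)
  s / sqrt(n)
}

#' Mean corolla depth of visited flowers, by sociality
#'
#' Computes, for each sociality group, the mean and standard error of the
#' corolla depth of visited flowers. With `weighting = "species"` (the
#' default) each bee species first gets its own mean visited depth and the
#' group statistics are taken across species; with `weighting = "visits"`
#' every visit counts equally and the statistics are taken across rows.
#' Both conventions are reported by `weighting = "both"`.
#'
#' @param tbl An interaction tibble with `corolla_mm`.
#' @param weighting `"species"`, `"visits"` or `"both"`.
#' @param sd_type As in [per_species_proportions()].
#' @return A tibble with `sociality`, `weighting`, `n` (species or
#'   visits), `mean_corolla_mm`, `se`.
#' @export
group_mean_corolla <- function(tbl, weighting = c("species", "visits", "both"),
                               sd_type = c("sample", "population")) {
  weighting <- match.arg(weighting)
  sd_type <- match.arg(sd_type)
  if (!"corolla_mm" %in% names(tbl)) {
    stop("`corolla_mm` column is required", call. = FALSE)
  }
  tbl <- tbl[!is.na(tbl$corolla_mm), ]
  by_species <- tbl |>
    dplyr::group_by(.data$bee_species, .data$sociality) |>
    dplyr::summarise(mean_depth = mean(.data$corolla_mm), .groups = "drop") |>
    dplyr::group_by(.data$sociality) |>
    dplyr::summarise(
      weighting = "species",
      n = dplyr::n(),
      mean_corolla_mm = mean(.data$mean_depth),
      se = group_se(.data$mean_depth, sd_type),
      .groups = "drop"
    )
  by_visits <- tbl |>
    dplyr::group_by(.data$sociality) |>
    dplyr::summarise(
      weighting = "visits",
      n = dplyr::n(),
      mean_corolla_mm = mean(.data$corolla_mm),
      se = group_se(.data$corolla_mm, sd_type),
      .groups = "drop"
    )
  switch(weighting,
    species = by_species,
    visits = by_visits,
    both = dplyr::bind_rows(by_species, by_visits)
  )
}

#' Visit shares by bee size class
#'
#' Bins bees by proboscis length (default classes 0-3, 3-6, 6-9, 9-12 mm,
#' lower bound included in the first bin, otherwise right-closed) and
#' reports, within each flower class, the share of visits contributed by
#' each size bin (shares sum to 1 within a flower class).
#'
#' @param tbl An interaction tibble with `proboscis_mm`.
#' @param breaks Bin edges in mm.
#' @param deep_threshold Passed to [code_complexity()].
#' @return A long tibble: `flower_class` (radial/bilateral and, when
#'   corolla data are present, shallow/deep), `proboscis_bin`, `n`,
#'   `share`.
#' @export
size_class_summary <- function(tbl, breaks = c(0, 3, 6, 9, 12),
                               deep_threshold = 3) {
  if (!"proboscis_mm" %in% names(tbl)) {
    stop("`proboscis_mm` column is required", call. = FALSE)
  }
  tbl <- code_complexity(tbl, deep_threshold) |>
    dplyr::filter(!is.na(.data$proboscis_mm))
  tbl$proboscis_bin <- cut(tbl$proboscis_mm, breaks = breaks,
                           include.lowest = TRUE, right = TRUE)
  tbl <- tbl[!is.na(tbl$proboscis_bin), ]
  one_class <- function(sub, label) {
    if (nrow(sub) == 0) return(NULL)
    sub |>
      dplyr::count(.data$proboscis_bin, .drop = FALSE) |>
      dplyr::mutate(flower_class = label, share = .data$n / sum(.data$n),
                    .before = 1)
  }
  out <- dplyr::bind_rows(
    one_class(tbl[!tbl$is_bilateral, ], "radial"),
    one_class(tbl[tbl$is_bilateral, ], "bilateral"),
    if (any(!is.na(tbl$is_deep))) {
      dplyr::bind_rows(
        one_class(tbl[!is.na(tbl$is_deep) & !tbl$is_deep, ], "shallow"),
        one_class(tbl[!is.na(tbl$is_deep) & tbl$is_deep, ], "deep")
      )
    }
  )
  tibble::as_tibble(out)
}

#' Logistic-regression stand-in for the phylogenetic choice model
#'
#' Fits a maximum-likelihood logistic regression of a binary flower-choice
#' response (bilateral vs radial, or deep vs shallow) on bee sociality,
#' proboscis length and their interaction, *without* random effects. This
#' deliberately ignores the phylogenetic (and repeated-measures)
#' correlation structure that a phylogenetic generalized linear mixed
#' model would carry, so its standard errors and Wald statistics are not
#' comparable to such a model's; it is a documented simplification whose
#' statistical behaviour is characterized by simulation in the test suite
#' (well-calibrated when species effects are independent, anti-
#' conservative when they carry phylogenetic signal).
#'
#' Rows with missing predictors or response are dropped (count reported
#' via a message). Visits are aggregated to binomial counts per species
#' before fitting, which leaves the likelihood unchanged. Complete or
#' quasi-complete separation is detected from fitted probabilities
#' numerically at 0/1 and flagged with a warning and the `separation`
#' field.
#'
#' @param tbl An interaction tibble.
#' @param response `"bilateral"` or `"deep"`.
#' @param deep_threshold Passed to [code_complexity()].
#' @return An object of class `choice_fit` wrapping the [stats::glm()]
#'   fit; supports [generics::tidy()] and [generics::glance()].
#' @export
fit_choice_regression <- function(tbl, response = c("bilateral", "deep"),
                                  deep_threshold = 3) {
  response <- match.arg(response)
  if (!"proboscis_mm" %in% names(tbl)) {
    stop("`proboscis_mm` column is required", call. = FALSE)
  }
  tbl <- code_complexity(tbl, deep_threshold)
  y <- if (response == "bilateral") tbl$is_bilateral else tbl$is_deep
  usable <- !is.na(y) & !is.na(tbl$proboscis_mm) & !is.na(tbl$sociality)
  n_dropped <- sum(!usable)
  if (n_dropped > 0) {
    message("dropped ", n_dropped, " record(s) with missing response or predictors")
  }
  dat <- tibble::tibble(
    bee_species = tbl$bee_species[usable],
    sociality = factor(tbl$sociality[usable],
                       levels = c("solitary", "eusocial")),
    proboscis_mm = tbl$proboscis_mm[usable],
    y = as.integer(y[usable])
  )
  agg <- dat |>
    dplyr::group_by(.data$bee_species, .data$sociality, .data$proboscis_mm) |>
    dplyr::summarise(k = sum(.data$y), n = dplyr::n(), .groups = "drop")
  fit <- stats::glm(cbind(k, n - k) ~ sociality * proboscis_mm,
                    family = stats::binomial(), data = agg)
  p <- stats::fitted(fit)
  separation <- !fit$converged || any(p < 1e-8 | p > 1 - 1e-8)
  if (separation) {
    warning("possible separation: fitted probabilities numerically 0 or 1; ",
            "coefficients are unreliable", call. = FALSE)
  }
  structure(
    list(fit = fit, response = response, n_visits = nrow(dat),
         n_species = nrow(agg), n_dropped = n_dropped,
         separation = separation),
    class = "choice_fit"
  )
}

#' @export
print.choice_fit <- function(x, ...) {
  cat(sprintf(
    "Logistic flower-choice model (response: %s; no phylogenetic correction)\n",
    x$response))
  cat(sprintf("  %d visits, %d species%s\n", x$n_visits, x$n_species,
              if (x$separation) "; WARNING: separation suspected" else ""))
  print(tidy(x))
  invisible(x)
}

#' @describeIn fit_choice_regression Coefficient table (term, estimate,
#'   std.error, statistic, p.value).
#' @param x A `choice_fit` object.
#' @param ... Unused.
#' @method tidy choice_fit
#' @export
tidy.choice_fit <- function(x, ...) {
  co <- summary(x$fit)$coefficients
  tibble::tibble(
    term = rownames(co),
    estimate = co[, "Estimate"],
    std.error = co[, "Std. Error"],
    statistic = co[, "z value"],
    p.value = co[, "Pr(>|z|)"]
  )
}

#' @describeIn fit_choice_regression One-row model summary.
#' @method glance choice_fit
#' @export
glance.choice_fit <- function(x, ...) {
  tibble::tibble(
    response = x$response,
    n_visits = x$n_visits,
    n_species = x$n_species,
    n_dropped = x$n_dropped,
    null.deviance = x$fit$null.deviance,
    deviance = x$fit$deviance,
    AIC = stats::AIC(x$fit),
    converged = x$fit$converged,
    separation = x$separation
  )
}

#' Descriptive report for an interaction table
#'
#' Convenience wrapper assembling the standard descriptives: visit counts
#' by symmetry and depth, species-level visit proportions to bilateral and
#' deep flowers by sociality, mean visited corolla depth by sociality
#' (both weightings), and visit shares by bee size class.
#'
#' @param tbl An interaction tibble.
#' @param deep_threshold Passed to [code_complexity()].
#' @param out_dir Optional directory; when given, each table is written as
#'   a CSV (`descriptives_*.csv`).
#' @return A named list of tibbles.
#' @export
interaction_descriptives <- function(tbl, deep_threshold = 3, out_dir = NULL) {
  out <- list(
    counts_symmetry = complexity_counts(tbl, "symmetry"),
    counts_depth = if ("corolla_mm" %in% names(tbl)) {
      complexity_counts(tbl, "depth", deep_threshold)
    },
    bilateral_by_sociality = per_species_proportions(tbl, "bilateral"),
    deep_by_sociality = if ("corolla_mm" %in% names(tbl)) {
      per_species_proportions(tbl, "deep", deep_threshold)
    },
    corolla_by_sociality = if ("corolla_mm" %in% names(tbl)) {
      group_mean_corolla(tbl, "both")
    },
    size_classes = if ("proboscis_mm" %in% names(tbl)) {
      size_class_summary(tbl, deep_threshold = deep_threshold)
    }
  )
  out <- Filter(Negate(is.null), out)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(out)) {
      readr::write_csv(out[[nm]],
                       file.path(out_dir, paste0("descriptives_", nm, ".csv")))
    }
  }
  out
}
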