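#' Specification for a synthetic bee-flower interaction table
#'
#' Describes the community and the visit model used by
#' [generate_interactions()]. Defaults mirror the margins of the field
#' dataset the analytics layer targets: 58 bee species of which 20 are
#' eusocial, 67 plant species, and roughly 187 visits per bee species
#' (about 10.8k rows in total), proboscis lengths around 4 mm and corolla
#' depths with a median near 3 mm.
#'
#' Each visit chooses a bilateral (and, independently, a deep-tubed)
#' flower with probability
#' `plogis(b0 + b1*eusocial + b2*proboscis + b3*eusocial*proboscis + u)`,
#' where `u` is a per-species random effect drawn from a Brownian-motion
#' model on a simulated ultrametric phylogeny, scaled so that
#' `phylo_signal` is the marginal variance at the tips.
#'
#' @param n_bee_species,n_plant_species Community sizes.
#' @param prop_eusocial Fraction of bee species that are eusocial (the
#'   realized count is `round(prop_eusocial * n_bee_species)`).
#' @param proboscis_meanlog,proboscis_sdlog Log-normal parameters of
#'   proboscis length (mm).
#' @param p_bilateral_plant Probability that a plant species is bilateral.
#' @param corolla_shape,corolla_scale Gamma parameters of corolla tube
#'   depth (mm).
#' @param beta0,beta_sociality,beta_proboscis,beta_interaction Visit-model
#'   coefficients on the logit scale (sociality coded 0 = solitary,
#'   1 = eusocial).
#' @param phylo_signal Tip variance of the Brownian species effect
#'   (`0` switches the effect off).
#' @param visits_mean,visits_dispersion Negative-binomial mean and
#'   dispersion (`size`) of the per-species visit count (floored at one
#'   visit per species).
#' @param n_rounds,n_plots Sampling design labels to attach to visits.
#' @param seed Mandatory integer seed; the generated table is a
#'   deterministic function of the spec.
#' @return An object of class `interaction_spec`.
#' @export
interaction_spec <- function(n_bee_species = 58,
                             n_plant_species = 67,
                             prop_eusocial = 20 / 58,
                             proboscis_meanlog = log(4),
                             proboscis_sdlog = 0.45,
                             p_bilateral_plant = 0.5,
                             corolla_shape = 2,
                             corolla_scale = 1.8,
                             beta0 = 0,
                             beta_sociality = 0,
                             beta_proboscis = 0,
                             beta_interaction = 0,
                             phylo_signal = 0,
                             visits_mean = 187,
                             visits_dispersion = 1.2,
                             n_rounds = 5,
                             n_plots = 6,
                             seed) {
  if (missing(seed) || !is.finite(seed)) {
    stop("`seed` is mandatory for a synthetic interaction spec", call. = FALSE)
  }
  stopifnot(
    n_bee_species >= 2, n_plant_species >= 4,
    prop_eusocial >= 0, prop_eusocial <= 1,
    p_bilateral_plant >= 0, p_bilateral_plant <= 1,
    proboscis_sdlog >= 0, corolla_shape > 0, corolla_scale > 0,
    phylo_signal >= 0, visits_mean > 0, visits_dispersion > 0
  )
  structure(
    list(
      n_bee_species = as.integer(n_bee_species),
      n_plant_species = as.integer(n_plant_species),
      prop_eusocial = prop_eusocial,
      proboscis_meanlog = proboscis_meanlog,
      proboscis_sdlog = proboscis_sdlog,
      p_bilateral_plant = p_bilateral_plant,
      corolla_shape = corolla_shape,
      corolla_scale = corolla_scale,
      beta0 = beta0,
      beta_sociality = beta_sociality,
      beta_proboscis = beta_proboscis,
      beta_interaction = beta_interaction,
      phylo_signal = phylo_signal,
      visits_mean = visits_mean,
      visits_dispersion = visits_dispersion,
      n_rounds = as.integer(n_rounds),
      n_plots = as.integer(n_plots),
      seed = as.integer(seed)
    ),
    class = "interaction_spec"
  )
}

# random ultrametric bifurcating tree with given tip labels, drawn from the
# current RNG stream
rcoal_labeled <- function(n, labels) {
  ape::rcoal(n, tip.label = labels)
}

#' Generate a random ultrametric phylogeny as a newick string
#'
#' A random bifurcating coalescent tree over the given number of species,
#' with contemporaneous (ultrametric) tips, serialized as newick. Stands
#' in for a literature genus-level bee phylogeny when simulating
#' phylogenetically correlated species effects.
#'
#' @param n_species Number of tips, `>= 2`.
#' @param seed Integer seed; the same seed yields an identical newick
#'   string.
#' @param labels Optional tip labels (default `bee_sp01`, `bee_sp02`, ...).
#' @return A single newick string.
#' @export
#' @examples
#' generate_tree(4, seed = 1)
generate_tree <- function(n_species, seed, labels = NULL) {
  if (n_species < 2) stop("`n_species` must be >= 2", call. = FALSE)
  if (is.null(labels)) {
    labels <- sprintf("bee_sp%02d", seq_len(n_species))
  }
  stopifnot(length(labels) == n_species)
  set.seed(seed)
  ape::write.tree(rcoal_labeled(n_species, labels))
}

# species effects ~ MVN(0, phylo_signal * C / tip_height): Brownian motion
# on the tree, normalized so the tip marginal variance equals phylo_signal
phylo_effects <- function(phy, phylo_signal) {
  n <- length(phy$tip.label)
  if (phylo_signal == 0) {
    return(stats::setNames(numeric(n), phy$tip.label))
  }
  C <- ape::vcv(phy)
  C <- C / mean(diag(C))
  u <- MASS::mvrnorm(1, mu = numeric(n), Sigma = phylo_signal * C)
  stats::setNames(as.numeric(u), colnames(C))[phy$tip.label]
}

#' Generate a synthetic bee-flower interaction table
#'
#' Simulates a bee community (sociality, proboscis length, phylogeny), a
#' plant community (symmetry, corolla depth; the first four plant species
#' are forced to cover all four symmetry-by-depth cells so that every
#' choice outcome has a flower to land on), and per-visit flower choices
#' under the logit model described in [interaction_spec()]. The bilateral
#' and deep choices share the coefficients and species effect but are
#' drawn independently, and the visited plant is sampled uniformly from
#' the plants in the chosen symmetry-by-depth cell, so the row-level
#' `symmetry`/`corolla_mm` columns reproduce the chosen flags exactly.
#'
#' @param spec An [interaction_spec()] (its `seed` makes the output a
#'   deterministic, byte-identical function of the spec).
#' @return An object of class `synthetic_interactions`: a list with
#'   `interactions` (tibble in the standard schema of
#'   [read_interactions()]), `bees`, `plants` (the generating trait
#'   tables), `tree` (newick string) and `truth` (the coefficients, the
#'   realized species effects `u`, the flags actually drawn, and the spec).
#' @export
#' @examples
#' synth <- generate_interactions(interaction_spec(
#'   n_bee_species = 6, n_plant_species = 8, visits_mean = 20, seed = 1
#' ))
#' head(synth$interactions)
generate_interactions <- function(spec) {
  stopifnot(inherits(spec, "interaction_spec"))
  set.seed(spec$seed)
  n_bee <- spec$n_bee_species
  bee_names <- sprintf("bee_sp%02d", seq_len(n_bee))
  genus <- sprintf("genus%02d", ceiling(seq_len(n_bee) / 3))
  n_euso <- round(spec$prop_eusocial * n_bee)
  sociality <- rep("solitary", n_bee)
  sociality[sample.int(n_bee, n_euso)] <- "eusocial"
  proboscis <- stats::rlnorm(n_bee, spec$proboscis_meanlog, spec$proboscis_sdlog)

  phy <- rcoal_labeled(n_bee, bee_names)
  u <- phylo_effects(phy, spec$phylo_signal)

  # plants: force one species into each symmetry-by-depth cell, rest random
  n_plant <- spec$n_plant_species
  plant_names <- sprintf("plant_sp%02d", seq_len(n_plant))
  bilateral <- c(FALSE, FALSE, TRUE, TRUE,
                 stats::runif(n_plant - 4) < spec$p_bilateral_plant)
  corolla <- numeric(n_plant)
  corolla[1] <- stats::runif(1, 0.5, 3)                                  # radial shallow
  corolla[2] <- 3 + stats::rgamma(1, spec$corolla_shape, scale = spec$corolla_scale) # radial deep
  corolla[3] <- stats::runif(1, 0.5, 3)                                  # bilateral shallow
  corolla[4] <- 3 + stats::rgamma(1, spec$corolla_shape, scale = spec$corolla_scale) # bilateral deep
  corolla[-(1:4)] <- stats::rgamma(n_plant - 4, spec$corolla_shape,
                                   scale = spec$corolla_scale)
  plants <- tibble::tibble(
    plant_species = plant_names,
    symmetry = ifelse(bilateral, "bilateral", "radial"),
    corolla_mm = corolla,
    is_deep = corolla > 3
  )

  n_visits <- pmax(1L, stats::rnbinom(n_bee, mu = spec$visits_mean,
                                      size = spec$visits_dispersion))
  idx <- rep(seq_len(n_bee), n_visits)
  total <- length(idx)
  euso <- as.numeric(sociality[idx] == "eusocial")
  prob_mm <- proboscis[idx]
  eta <- spec$beta0 + spec$beta_sociality * euso +
    spec$beta_proboscis * prob_mm +
    spec$beta_interaction * euso * prob_mm + u[bee_names[idx]]
  p <- stats::plogis(eta)
  choose_bilateral <- stats::rbinom(total, 1, p) == 1
  choose_deep <- stats::rbinom(total, 1, p) == 1

  cell <- 2 * choose_bilateral + choose_deep
  plant_id <- integer(total)
  for (cc in 0:3) {
    members <- which(plants$symmetry == ifelse(cc >= 2, "bilateral", "radial") &
                       plants$is_deep == (cc %% 2 == 1))
    sel <- cell == cc
    if (any(sel)) {
      plant_id[sel] <- members[sample.int(length(members), sum(sel),
                                          replace = TRUE)]
    }
  }

  interactions <- tibble::tibble(
    bee_species = bee_names[idx],
    bee_genus = genus[idx],
    sociality = sociality[idx],
    proboscis_mm = prob_mm,
    plant_species = plants$plant_species[plant_id],
    symmetry = plants$symmetry[plant_id],
    corolla_mm = plants$corolla_mm[plant_id],
    round = sample.int(spec$n_rounds, total, replace = TRUE),
    plot = sample.int(spec$n_plots, total, replace = TRUE)
  )

  structure(
    list(
      interactions = interactions,
      bees = tibble::tibble(
        bee_species = bee_names, bee_genus = genus, sociality = sociality,
        proboscis_mm = proboscis, u = as.numeric(u[bee_names]),
        n_visits = as.integer(n_visits)
      ),
      plants = plants,
      tree = ape::write.tree(phy),
      truth = list(
        coefficients = c(
          intercept = spec$beta0,
          sociality = spec$beta_sociality,
          proboscis = spec$beta_proboscis,
          interaction = spec$beta_interaction
        ),
        u = u,
        n_bilateral = sum(choose_bilateral),
        n_deep = sum(choose_deep),
        choose_bilateral = choose_bilateral,
        choose_deep = choose_deep,
        spec = spec
      )
    ),
    class = "synthetic_interactions"
  )
}

#' @export
print.synthetic_interactions <- function(x, ...) {
  cat(sprintf(
    "Synthetic interaction table: %d visits, %d bee species (%d eusocial), %d plant species\n",
    nrow(x$interactions), nrow(x$bees),
    sum(x$bees$sociality == "eusocial"), nrow(x$plants)))
  cat(sprintf("  visit-model coefficients: %s; phylo_signal = %g; seed = %d\n",
              paste(sprintf("%s=%g", names(x$truth$coefficients),
                            x$truth$coefficients), collapse = ", "),
              x$truth$spec$phylo_signal, x$truth$spec$seed))
  invisible(x)
}

#' Write a synthetic interaction dataset to disk
#'
#' Writes `interactions.csv` (standard schema), `tree.nwk` and
#' `truth.json` into `out_dir`.
#'
#' @param synth A `synthetic_interactions` object.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_synthetic <- function(synth, out_dir) {
  stopifnot(inherits(synth, "synthetic_interactions"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(out_dir, "interactions.csv")
  p2 <- file.path(out_dir, "tree.nwk")
  p3 <- file.path(out_dir, "truth.json")
  readr::write_csv(synth$interactions, p1)
  writeLines(synth$tree, p2)
  truth <- synth$truth
  truth$spec <- unclass(truth$spec)
  truth$u <- as.list(truth$u)
  truth$choose_bilateral <- NULL
  truth$choose_deep <- NULL
  jsonlite::write_json(truth, p3, auto_unbox = TRUE, digits = NA)
  invisible(c(p1, p2, p3))
}
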