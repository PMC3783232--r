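# Shared fixtures, all built in code.

# histogram of Gaussian peaks on an integer channel grid
gaussian_histogram <- function(means, cvs, n_events, channels = 1:512,
                               seed = NULL, background = 0) {
  if (!is.null(seed)) set.seed(seed)
  counts <- numeric(length(channels))
  breaks <- c(channels - 0.5, max(channels) + 0.5)
  for (i in seq_along(means)) {
    ev <- rnorm(n_events[[min(i, length(n_events))]], means[[i]],
                cvs[[min(i, length(cvs))]] / 100 * means[[i]])
    ev <- pmin(pmax(ev, breaks[1]), breaks[length(breaks)] - 1e-9)
    counts <- counts + tabulate(findInterval(ev, breaks),
                                nbins = length(channels))
  }
  if (background > 0) counts <- counts + rpois(length(channels), background)
  tibble::tibble(channel = channels, count = counts)
}

# single-cytotype, single-pathway config for focused tests
tiny_config <- function(pathway = "SEXUAL", ploidy = 4, n_plants = 5,
                        peak_cv = 0, rng_seed = 1, ...) {
  probs <- setNames(list(setNames(as.numeric(pathway_levels() == pathway),
                                  pathway_levels())),
                    as.character(ploidy))
  sim_config(
    populations = tibble::tibble(population_id = "pop1", ploidy_x = ploidy,
                                 n_plants = n_plants),
    pathway_probs = probs, peak_cv = peak_cv, rng_seed = rng_seed, ...)
}

# mode matrix straight from counts
mm <- function(n_sexual, n_apomictic) {
  tibble::tibble(plant_id = paste0("p", seq_along(n_sexual)),
                 n_sexual = n_sexual, n_apomictic = n_apomictic)
}
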