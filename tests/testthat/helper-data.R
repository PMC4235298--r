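# shared fixtures built in code

# a miniature but complete study configuration used where full default
# scale is not needed
small_config <- function(seed = 1L, ...) {
  synthetic_config(
    seed = seed, n_plots = 8L, pool_size = 40L, richness_range = c(12L, 20L),
    n_focal = 5L, saplings_range = c(2L, 4L), ...
  )
}

# a small trait table with known values and one missing cell
tiny_traits <- function() {
  tibble::tibble(
    species = c("alpha", "beta", "gamma", "delta"),
    LA = c(100, 200, 300, 400),
    SLA = c(10, 12, 14, 16),
    LDMC = c(250, 300, 350, NA),
    C = c(40, 44, 48, 50),
    CN = c(20, 25, 30, 35),
    CP = c(300, 350, 400, 450),
    PHEN = c(0.02, 0.04, 0.06, 0.08)
  )
}

# direct simulation of mixed-model data (bypassing the study generator) for
# fitter-focused tests: plot-level predictors, crossed random intercepts,
# integer binomial successes
sim_glmm_data <- function(n, beta, intercept = qlogis(0.1),
                          sigma_species = 0.3, sigma_plot = 0.3,
                          sigma_obs = 0.3, n_species = 8, n_plots = 20,
                          w_range = c(10, 60)) {
  species <- sample(paste0("sp", seq_len(n_species)), n, replace = TRUE)
  plot <- sample(paste0("pl", seq_len(n_plots)), n, replace = TRUE)
  X <- matrix(rnorm(n * length(beta)), n)
  colnames(X) <- names(beta)
  b_sp <- stats::setNames(rnorm(n_species, 0, sigma_species),
                          paste0("sp", seq_len(n_species)))
  b_pl <- stats::setNames(rnorm(n_plots, 0, sigma_plot),
                          paste0("pl", seq_len(n_plots)))
  eta <- intercept + drop(X %*% beta) + b_sp[species] + b_pl[plot] +
    rnorm(n, 0, sigma_obs)
  w <- sample(seq(w_range[1], w_range[2]), n, replace = TRUE)
  y <- rbinom(n, w, plogis(eta)) / w
  out <- tibble::tibble(species = species, plot = plot,
                        obs = paste0("o", seq_len(n)), y = y, w = w)
  dplyr::bind_cols(out, tibble::as_tibble(X))
}
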