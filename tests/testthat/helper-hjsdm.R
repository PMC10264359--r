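# Shared fixtures, built in code.

# toy community table: explicit counts, valid schema
toy_community <- function(counts, years = 2000, depth = NULL) {
  n <- nrow(counts)
  if (is.null(depth)) depth <- seq(20, 200, length.out = n)
  df <- data.frame(haul_id = sprintf("h%03d", seq_len(n)),
                   lon = seq(13, 16, length.out = n),
                   lat = seq(42, 45, length.out = n),
                   year = rep_len(years, n),
                   depth = depth,
                   bot_temp = seq(10, 20, length.out = n),
                   seabed = rep_len(c("mud_to_muddy_sand", "sand"), n),
                   swept_area = rep(0.047, n),
                   stringsAsFactors = FALSE)
  cbind(df, as.data.frame(counts))
}

toy_traits <- function(p, species = paste0("s", seq_len(p))) {
  data.frame(species = species,
             age_maturity = seq(3, 12, length.out = p),
             repro_mode = rep_len(c(0L, 1L), p),
             trophic_level = seq(3.2, 4.2, length.out = p))
}

toy_taxonomy <- function(p, species = paste0("s", seq_len(p))) {
  data.frame(species = species,
             phylum = "Chordata", class = "Chondrichthyes",
             order = paste0("ord", rep(seq_len(max(1, ceiling(p / 3))), each = 3)[seq_len(p)]),
             family = paste0("fam", rep(seq_len(max(1, ceiling(p / 2))), each = 2)[seq_len(p)]),
             genus = paste0("gen", seq_len(p)),
             species_name = paste0("sp", seq_len(p)),
             stringsAsFactors = FALSE)
}

# small scenario used for fast end-to-end fits
small_scenario <- function(seed = 4, n_hauls = 200, years = 2000:2003, ...) {
  hjsdm_scenario(n_hauls = n_hauls, years = years, seed = seed, ...)
}

# one shared small fitted model per test session (fits in a few seconds)
shared_fit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- simulate_community(small_scenario())
      cache <<- hjsdm(sim$community, traits = adriatic_traits(),
                      taxonomy = adriatic_taxonomy(),
                      mcmc = mcmc_control(n_chains = 2, n_iter = 300,
                                          n_burnin = 100, thin = 2, seed = 7,
                                          n_factors_max = 2))
      attr(cache, "sim") <<- sim
    }
    cache
  }
})

# the full-scale recovery fit (1500 hauls, desk-scale MCMC defaults),
# fitted once and shared by the end-to-end test blocks
recovery_fit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- simulate_community(hjsdm_scenario(n_hauls = 1500, seed = 101))
      fit <- hjsdm(sim$community, traits = adriatic_traits(),
                   taxonomy = adriatic_taxonomy(),
                   mcmc = mcmc_control(seed = 11))
      cache <<- list(sim = sim, fit = fit)
    }
    cache
  }
})

# hand-assembled minimal hjsdm object with controlled posterior draws, for
# summary/prediction arithmetic tests
fake_fit <- function(B_pa, B_abu = B_pa, X, groups, species, traits = NULL,
                     rho_pa = numeric(0), rho_abu = numeric(0),
                     Gamma_pa = NULL, Gamma_abu = NULL,
                     sigma_abu = NULL, m = NULL, s = NULL,
                     levels_pa = list(), levels_abu = list(),
                     years = 2000, coords_km = NULL, community = NULL) {
  nd <- dim(B_pa)[3]
  p <- length(species)
  if (is.null(traits)) traits <- toy_traits(p, species)
  if (is.null(Gamma_pa)) Gamma_pa <- array(0, c(4, nrow(B_pa), nd))
  if (is.null(Gamma_abu)) Gamma_abu <- Gamma_pa
  if (is.null(sigma_abu)) sigma_abu <- matrix(0, p, nd)
  if (is.null(m)) m <- rep(0, p)
  if (is.null(s)) s <- rep(1, p)
  dimnames(B_pa) <- dimnames(B_abu) <- list(colnames(X), species, NULL)
  post <- function(B, Gamma, rho, levels) {
    structure(list(family = "any", B = B, Gamma = Gamma,
                   V = array(diag(nrow(B)), c(nrow(B), nrow(B), nd)),
                   rho = if (length(rho)) rho else rep(0, nd),
                   sigma = sigma_abu, chain = rep(1L, nd), n_draws = nd,
                   levels = levels),
              class = "hjsdm_post")
  }
  structure(list(
    pa = post(B_pa, Gamma_pa, rho_pa, levels_pa),
    abu = post(B_abu, Gamma_abu, rho_abu, levels_abu),
    design = structure(list(X = X, groups = groups,
                            year_mean = mean(years)), class = "hjsdm_design"),
    hurdle = list(scale_params = data.frame(species = species, m = m, s = s,
                                            n_presence = rep(2L, p))),
    traits = traits, species = species,
    centre = c(14, 43),
    coords_km = if (is.null(coords_km)) cbind(x = rep(0, nrow(X)), y = rep(0, nrow(X)))
                else coords_km,
    years = years, year_mean = mean(years), community = community),
    class = "hjsdm")
}

# grid covering the default scenario's covariate ranges
toy_grid <- function(n = 4, year = 2000) {
  data.frame(cell_id = seq_len(n),
             lon = seq(13, 15, length.out = n),
             lat = seq(42.5, 44.5, length.out = n),
             year = year,
             depth = seq(30, 110, length.out = n),
             bot_temp = seq(12, 18, length.out = n),
             seabed = rep_len(c("sand", "mud_to_muddy_sand"), n),
             cell_area = cell_areas(seq(42.5, 44.5, length.out = n)))
}
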