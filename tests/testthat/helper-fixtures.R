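# shared fixtures, built once per test run and cached

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# small labeled spectra table with both classes, deterministic content
tiny_spectra <- function(n_per_class = 5, n_wl = 8, seed = 42) {
  withr::with_seed(seed, {
    n <- 2 * n_per_class
    m <- matrix(rnorm(n * n_wl), n, n_wl)
    new_spectra(m, seq(1100, by = 50, length.out = n_wl),
                rep(c(0L, 1L), each = n_per_class))
  })
}

# two materials identical except for the amplitude of two planted bands at
# 1450 and 1940 nm; everything else (baseline, widths) matches, so those two
# bands carry all the class information
planted_two_band_spectra <- function(n = 60, grid = default_grid(157), seed = 5,
                                     scatter_sd = 0.02) {
  veg <- material_profile(
    "wet", "vegetable",
    data.frame(center = c(1450, 1940), width = c(40, 50), amplitude = c(0.6, 0.9)),
    baseline_offset = 0.3, baseline_slope = 0.1,
    scatter_sd = scatter_sd, noise_sd = 0.01)
  dry <- material_profile(
    "dry", "fm",
    data.frame(center = c(1450, 1940), width = c(40, 50), amplitude = c(0.1, 0.15)),
    baseline_offset = 0.3, baseline_slope = 0.1,
    scatter_sd = scatter_sd, noise_sd = 0.01)
  simulate_spectra(list(list(profile = veg, n = n), list(profile = dry, n = n)),
                   grid, seed = seed)
}

# the standard discrimination suite: vegetables vs plastics on a 157-point
# grid; water bands at 1450/1940 nm are the dominant class contrast
recovery_spectra <- function() {
  cached("recovery_spectra", function() {
    simulate_spectra(
      sample_plan(vegetable_leaf = 50, vegetable_root = 50,
                  plastic_pe = 50, plastic_pet = 50),
      default_grid(157), seed = 11)
  })
}

# all five selectors run on the recovery suite (shared by the selection
# unit tests and the acceptance suite)
recovery_selections <- function() {
  cached("recovery_selections", function() {
    s <- recovery_spectra()
    n_lv <- as.integer(choose_n_lv(s, max_lv = 5, folds = 5, seed = 1,
                                   autoscale = TRUE))
    wrc_model <- fit_plsda(s, n_lv = n_lv, autoscale = TRUE)
    list(
      wrc = wrc_select(wrc_model, k = 5, min_separation = 30),
      vip = vip_select(s, folds = 5, seed = 2),
      sfs = sfs_select(s, max_features = 4, folds = 10, seed = 3),
      spa = spa_select(s, min_vars = 2, max_vars = 5, folds = 5, seed = 4,
                       starts = seq(1, 157, by = 4)),
      ipls = ipls_select(s, interval_width = 1, max_intervals = 3,
                         folds = 5, seed = 5)
    )
  })
}

quiet_presets <- function() {
  lapply(material_presets(), function(p) {
    p$scatter_sd <- 0
    p$noise_sd <- 0
    p
  })
}

six_bands <- c(1150, 1400, 1450, 1731, 1880, 1920)
five_bands <- c(1150, 1400, 1731, 1880, 1920)

# two noiseless scenes + matching noiseless training spectra
zero_noise_imaging <- function() {
  cached("zero_noise_imaging", function() {
    qp <- quiet_presets()
    bands <- default_imaging_bands()
    cubes <- lapply(1:2, function(i) {
      sc <- demo_scene(qp, lines = 48L, pixels = 48L, variant = i)
      sc$background_noise_sd <- 0
      simulate_hypercube(sc, bands, seed = 100 + i)
    })
    training <- simulate_spectra(
      sample_plan(vegetable_leaf = 30, vegetable_root = 30, plastic_pe = 15,
                  wood = 15, paper = 15, stone = 15, rubber = 15,
                  film_mimic = 15, presets = qp),
      bands, seed = 50)
    list(cubes = cubes, training = training)
  })
}

# four scenes at the presets' calibrated noise + noisy training spectra
noisy_imaging <- function() {
  cached("noisy_imaging", function() {
    bands <- default_imaging_bands()
    cubes <- lapply(1:4, function(i) {
      simulate_hypercube(demo_scene(lines = 48L, pixels = 48L, variant = i),
                         bands, seed = 200 + i)
    })
    training <- simulate_spectra(
      sample_plan(vegetable_leaf = 30, vegetable_root = 30, plastic_pe = 15,
                  wood = 15, paper = 15, stone = 15, rubber = 15,
                  film_mimic = 15),
      bands, seed = 51)
    list(cubes = cubes, training = training)
  })
}

# independent stratified-CV scorer for PLS-DA subsets, used as the oracle
# against the selectors' internal scan (same fold primitive, own loop)
oracle_subset_score <- function(spectra, subset, folds, seed, max_lv = 5) {
  subset <- sort(unique(subset))
  cols <- c("sample_id", "label",
            setdiff(names(spectra), c("sample_id", "label"))[subset])
  sub <- spectra[, cols]
  fold_id <- nirfm:::stratified_folds(sub$label, folds, seed)
  errs <- mses <- numeric(max(fold_id))
  for (f in seq_len(max(fold_id))) {
    train <- sub[fold_id != f, ]
    test <- sub[fold_id == f, ]
    a <- min(length(subset), max_lv, nrow(train) - 1)
    pred <- predict(fit_plsda(train, n_lv = a), test)
    errs[f] <- mean(pred$predicted != pred$label)
    mses[f] <- mean((pred$score - pred$label)^2)
  }
  c(error = mean(errs), mse = mean(mses))
}
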