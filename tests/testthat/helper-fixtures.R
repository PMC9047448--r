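# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, make) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- make()
  .fixtures[[name]]
}

# 5-bin grid for tiny exact-oracle tests
tiny_grid <- function() bin_grid(600, 601, 0.2)

# small panel spread over the tiny grid's bins
tiny_panel <- function() {
  lipid_panel(sprintf("L%d", 1:5), c(600.1, 600.3, 600.5, 600.7, 600.9))
}

# 14-class profiles at the default separation
profiles14 <- function() {
  fixture("profiles14", function() make_profiles(14, separation = 1, seed = 1))
}

# the evaluation-regime library: 14 classes x 16 cells, noise CV 0.05
library14x16 <- function() {
  fixture("library14x16", function() {
    synth_library(profiles14(), 16, noise_cv = 0.05, seed = 2)
  })
}

# small 3-class library for fast model tests
library3 <- function() {
  fixture("library3", function() {
    synth_library(make_profiles(3, separation = 1, seed = 3), 6,
                  noise_cv = 0.05, seed = 4)
  })
}

# tissue image with 30% necrosis plus its fitted 14-class model
tissue_case <- function() {
  fixture("tissue_case", function() {
    model <- fit_model(library14x16(), "CELL_LINE")
    tt <- synth_tissue_image(profiles14()[[1]], necrotic_fraction = 0.3,
                             dims = c(64, 64), noise_cv = 0.05, seed = 4)
    list(model = model, image = tt$image, truth = tt$truth)
  })
}

# random valid centroid spectrum for property loops
random_spectrum <- function(n = 30, seed = 1) {
  set.seed(seed)
  mz <- sort(runif(n, 600, 950))
  while (any(diff(mz) <= 0)) mz <- sort(runif(n, 600, 950))
  centroid_spectrum(mz, rlnorm(n))
}
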