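# Expensive shared fixtures, built once per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache, inherits = FALSE))
    assign(name, builder(), envir = .fixture_cache)
  get(name, envir = .fixture_cache, inherits = FALSE)
}

# small labeled training fixture + model, shared across classification,
# quantification and acceptance tests
small_fixture <- function()
  cached("small_fixture", function()
    make_training_fixture(n_crystals = 400, seed = 11, n_images = 4,
                          image_size = 768))

small_model <- function()
  cached("small_model", function() train_classifier(small_fixture(), seed = 1)$model)

# a mid-size scene with all four classes, shared by several tests
demo_scene <- function()
  cached("demo_scene", function()
    render_scene(scene_spec(image_size = 512L, n_com = 25, n_cod = 6,
                            n_nd = 5, n_noise = 5, overlap_probability = 0,
                            seed = 42)))

# noise-free scene conditions: no sensor noise, no illumination/focus/
# background jitter, no debris-class objects, non-touching placement
clean_spec <- function(n_com = 10, n_cod = 3, n_nd = 0, seed = 1,
                       image_size = 384L, ...)
  scene_spec(image_size = image_size, n_com = n_com, n_cod = n_cod,
             n_nd = n_nd, n_noise = 0, overlap_probability = 0,
             noise_sd = 0, focus_jitter = 0, illumination_amplitude = 0,
             background_jitter = 0, seed = seed, ...)

# a 15-column feature table with class structure encoded in every feature:
# class k drawn from N(k * d, 1)
gaussian_feature_table <- function(n_per_class, d, classes = c(0L, 1L),
                                   seed = 99) {
  set.seed(seed)
  tabs <- lapply(seq_along(classes), function(i) {
    x <- matrix(stats::rnorm(n_per_class * 15, mean = (i - 1) * d, sd = 1),
                n_per_class, 15, dimnames = list(NULL, feature_names()))
    cbind(as.data.frame(x), class = classes[i])
  })
  out <- do.call(rbind, tabs)
  out[sample(nrow(out)), ]
}

# disc mask helper
disc_mask <- function(radius, pad = 4L) {
  n <- 2L * (radius + pad) + 1L
  ctr <- radius + pad + 1L
  d <- sqrt((row(matrix(0, n, n)) - ctr)^2 + (col(matrix(0, n, n)) - ctr)^2)
  d <= radius
}

# minimal labeled crystal table for quantification tests
toy_crystals <- function(areas, classes, experiment = "E1", compound = "cmpd",
                         conc = 0, well = "W1", fields = 1L) {
  data.frame(experiment_id = experiment, well_id = well,
             field_index = rep_len(fields, length(areas)),
             compound = compound, concentration_nM = conc,
             area = areas, class = classes)
}
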