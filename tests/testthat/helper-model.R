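# Shared fixtures. The calibrated activation model is computed once per
# test run and cached; all VTA tests use the default study configuration
# (0.5 mm lattice, 30-degree planes, 0.1 mm voxels) unless a test says
# otherwise.

.fixtures <- new.env()

test_geometry <- function() lead_geometry()
test_tissue <- function() tissue_model()
test_grid <- function() axon_grid_spec()

test_model <- function() {
  if (is.null(.fixtures$model)) {
    .fixtures$model <- calibrate_threshold(test_geometry(), test_tissue(),
                                           test_grid())
  }
  .fixtures$model
}

test_z0 <- function() level_z(test_geometry())

build_micc <- function(distribution, amplitude) {
  build_vta(make_sources(test_geometry(), distribution, amplitude),
            test_model(), test_grid())
}

# small deterministic voxel blob for metric tests
random_blob <- function(n = 200, spread = 20, seed = 1) {
  set.seed(seed)
  ijk <- unique(cbind(sample(-spread:spread, n, TRUE),
                      sample(-spread:spread, n, TRUE),
                      sample(0:2, n, TRUE)))
  vta_from_voxels(ijk, 0.1)
}

# reduced experiment grid shared by the pipeline and acceptance tests
# (three target radii spanning the study range; full fractionalization set)
.reduced_grid_results <- function() {
  if (is.null(.fixtures$grid_results)) {
    cfg <- grid_config(target_radii = c(2, 3, 4), model = test_model())
    .fixtures$grid_results <- run_grid(cfg)
  }
  .fixtures$grid_results
}
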