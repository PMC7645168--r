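# Shared fixtures.  Expensive objects are built lazily and cached for the
# whole test session.

.fixtures <- new.env(parent = emptyenv())

# small grid for operator-level tests
tiny_grid <- function(n = 32) voxel_grid(c(n, n, n), c(1, 1, 1))

# a tiny phantom preset used for fast end-to-end tests: same anatomy and
# sphere inserts as the default, on a 64x64x48 grid
tiny_spec <- function(spheres = default_spheres()) {
  phantom_spec(grid = voxel_grid(c(64, 64, 48), c(1, 1, 1.5)),
               spheres = spheres)
}

# noiseless tiny dataset, cached
tiny_noiseless <- function() {
  if (is.null(.fixtures$tiny_noiseless))
    .fixtures$tiny_noiseless <- simulate_stage(tiny_spec(), snr = Inf, seed = 7)
  .fixtures$tiny_noiseless
}

# noisy tiny dataset, cached
tiny_noisy <- function() {
  if (is.null(.fixtures$tiny_noisy))
    .fixtures$tiny_noisy <- simulate_stage(tiny_spec(), snr = 10, seed = 7)
  .fixtures$tiny_noisy
}

# full desk-scale noisy dataset and its multi-echo reconstruction (the same
# conditions the quantitative evaluation reports): built once, shared by the
# acceptance tests
desk_run <- function() {
  if (is.null(.fixtures$desk_run)) {
    ds <- simulate_stage(phantom_spec(), snr = 10, seed = 20260930L)
    rec <- run_stage_pipeline(ds, masks = "ideal")
    K <- make_dipole_kernel(ds$grid)
    tes <- lapply(ds$echoes, function(e) e$te_s)
    chi_iswim <- fuse_echoes(lapply(rec$fields, function(f)
      iswim_inversion(f, K) * ds$brain_mask), tes, rec$r2star)
    .fixtures$desk_run <- list(ds = ds, rec = rec, chi_iswim = chi_iswim)
  }
  .fixtures$desk_run
}

# two identically seeded demo runs on the tiny phantom (reproducibility and
# report-schema checks share them), cached
demo_pair <- function() {
  if (is.null(.fixtures$demo_pair)) {
    d1 <- file.path(tempdir(), "demo1"); d2 <- file.path(tempdir(), "demo2")
    r1 <- run_demo(seed = 5, out_dir = d1, spec = tiny_spec())
    r2 <- run_demo(seed = 5, out_dir = d2, spec = tiny_spec())
    .fixtures$demo_pair <- list(first = r1, second = r2,
                                tsv1 = file.path(d1, "report.tsv"),
                                tsv2 = file.path(d2, "report.tsv"))
  }
  .fixtures$demo_pair
}

# uniform sphere in a cubic volume; analytic exterior field oracle lives in
# the tests that use it
sphere_chi <- function(n, radius_vox, chi_ppb = 1000) {
  g <- voxel_grid(c(n, n, n), c(1, 1, 1))
  co <- scswim:::world_coords(g)
  ctr_idx <- floor(n / 2) + 1L
  ctr_world <- co[[1]][ctr_idx]          # exactly on a voxel center
  q <- scswim:::ellipsoid_q(co, rep(ctr_world, 3), rep(radius_vox, 3))
  chi <- array(0, g$shape)
  chi[q < 1] <- chi_ppb
  list(chi = chi, grid = g, center = rep(ctr_idx, 3))
}
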