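## Shared fixtures: small, fast phantom configurations for unit tests.
## The package defaults describe a realistic 30 mm tumour; unit tests use a
## scaled-down grid so each file stays fast.

small_phantom_spec <- function(seed = 1L, ...) {
  args <- list(grid_shape = c(24, 24, 8), tumour_axes = c(9, 9, 9),
               seed = seed)
  do.call(phantom_spec, utils::modifyList(args, list(...)))
}

## Voxel table straight from a phantom (normalised volume + entropy map).
phantom_table <- function(ph, id = "P001", econf = entropy_config()) {
  nv <- normalize_grayscale(ph$volume, ph$mask)
  ent <- entropy_map(nv, ph$mask, econf)
  build_voxel_table(nv, ent, ph$mask, id)
}

## Pooled z-scored feature matrix for a list of voxel tables.
pooled_features <- function(tables) {
  tr <- fit_voxel_zscore(tables)
  list(transform = tr,
       features = do.call(rbind, lapply(tables, function(t) {
         tz <- apply_voxel_zscore(t, tr)
         as.matrix(tz[, c("z_intensity", "z_entropy")])
       })))
}
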