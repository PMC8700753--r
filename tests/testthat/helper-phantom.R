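# Shared phantom cases, generated once per test run.

.phantom_cache <- new.env(parent = emptyenv())

cached_phantom <- function(key, cfg) {
  if (is.null(.phantom_cache[[key]]))
    .phantom_cache[[key]] <- generate_phantom(cfg)
  .phantom_cache[[key]]
}

default_phantom <- function() cached_phantom("default", phantom_config())

noiseless_phantom <- function()
  cached_phantom("noiseless", phantom_config(noise_sd = 0, seed = 11))

defect_phantom <- function()
  cached_phantom("defect", phantom_config(defect_enabled = TRUE,
                                          protrusion_height_mm = 0,
                                          fissure_enabled = FALSE,
                                          seed = 12))

bridge_phantom <- function()
  cached_phantom("bridge", phantom_config(ssb_cleft_planes = "bridge",
                                          seed = 13))

clean_phantom <- function()
  cached_phantom("clean", phantom_config(fissure_enabled = FALSE,
                                         protrusion_height_mm = 0,
                                         ssb_cleft_planes = "none",
                                         sclerosis_enabled = FALSE,
                                         seed = 14))

default_frame <- function() anatomical_frame()

segment_phantom_cartilage <- function(ph)
  segment_by_threshold(ph$mri, threshold_spec(150, 1e6,
                                              min_volume_mm3 = 30),
                       "cartilage")

segment_phantom_ct_bone <- function(ph)
  segment_by_threshold(ph$ct, threshold_spec(500, 1e6,
                                             min_volume_mm3 = 30),
                       "humerus")

# numeric surface-area oracle: area of the sphere-of-radius-R patch whose
# AP projection is the ellipse with the given centre and semi-axes
spherical_patch_area <- function(R, centre_uv, semi_uv, step = 0.02) {
  us <- seq(centre_uv[1] - semi_uv[1], centre_uv[1] + semi_uv[1],
            by = step)
  vs <- seq(centre_uv[2] - semi_uv[2], centre_uv[2] + semi_uv[2],
            by = step)
  g <- expand.grid(u = us, v = vs)
  inside <- ((g$u - centre_uv[1]) / semi_uv[1])^2 +
    ((g$v - centre_uv[2]) / semi_uv[2])^2 <= 1
  w <- sqrt(pmax(R^2 - g$u[inside]^2 - g$v[inside]^2, 1e-9))
  sum(R / w) * step^2
}

# brute-force voxel-counting coverage oracle: a footprint raster point is
# covered when any sample along the AP column through it lies inside one
# of the graft solids (analytic membership, independent of the
# silhouette-based implementation)
coverage_oracle <- function(footprint, frame, grafts, poses,
                            resolution = 0.2, z_step = 0.25) {
  fuv <- capfuse:::project_ap(frame, footprint)
  hull <- grDevices::chull(fuv[, 1], fuv[, 2])
  hx <- fuv[hull, 1]; hy <- fuv[hull, 2]
  us <- seq(min(hx), max(hx), by = resolution)
  vs <- seq(min(hy), max(hy), by = resolution)
  gr <- expand.grid(u = us, v = vs)
  in_fp <- capfuse:::point_in_polygon(gr$u, gr$v, hx, hy)
  gu <- gr$u[in_fp]; gv <- gr$v[in_fp]
  covered <- rep(FALSE, length(gu))
  for (i in seq_along(grafts)) {
    gvtx <- apply_transform(poses[[i]], grafts[[i]]$mesh$vertices)
    zr <- range(capfuse:::project_axis(frame, gvtx))
    zs <- seq(zr[1] - z_step, zr[2] + z_step, by = z_step)
    for (z in zs) {
      pts <- sweep(outer(gu, frame$ml) + outer(gv, frame$pd) +
                     outer(rep(z, length(gu)), frame$ap),
                   2, frame$origin, `+`)
      covered <- covered | capfuse:::graft_contains(grafts[[i]],
                                                    poses[[i]], pts)
    }
  }
  mean(covered)
}
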