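# Cached phantoms (building at 2 mm takes ~1.5 s; reuse across tests)
.cache <- new.env(parent = emptyenv())

ref_phantom <- function(sex = "male") {
  key <- paste0("ph_", sex)
  if (is.null(.cache[[key]]))
    .cache[[key]] <- build_reference_phantom(sex, voxel_mm = 2)
  .cache[[key]]
}

# uniform block "phantom" of one material for transport oracles
uniform_block <- function(material_name = "water", n = c(40, 40, 40),
                          voxel_mm = 5, density = NULL) {
  mat <- material_from_table(material_name)
  if (!is.null(density)) mat$density <- density
  v_cc <- (voxel_mm / 10)^3
  nv <- prod(n)
  organs <- data.frame(id = 1L, organ = material_name, side = "none",
                       material = material_name, target_cc = NA_real_,
                       n_vox = nv, volume_cc = nv * v_cc,
                       mass_g = nv * v_cc * mat$density)
  mats <- list(material_from_table("air"), mat)
  names(mats) <- c("air", material_name)
  structure(list(labels = array(1L, dim = n), voxel_mm = voxel_mm,
                 origin_mm = -n * voxel_mm / 2, sex = "male",
                 organs = organs, materials = mats),
            class = "phantom")
}

# voxel z-indices of an organ
organ_z <- function(ph, organ) {
  idx <- which(ph$labels == ph$organs$id[match(organ, ph$organs$organ)])
  nxy <- prod(dim(ph$labels)[1:2])
  (idx - 1L) %/% nxy + 1L
}

organ_voxels <- function(ph, organ)
  which(ph$labels == ph$organs$id[match(organ, ph$organs$organ)])

# first-flight distances through a phantom (dir = c(0,0,0) -> isotropic)
first_flight_acc <- function(ph, origin_mm, dir, energy_kev, n, seed) {
  ctx <- pedidose:::.transport_context(ph)
  pedidose:::cpp_first_flight(
    as.integer(ph$labels), dim(ph$labels), ph$voxel_mm, ctx$mat_of_label,
    ctx$mu$energy_kev, ctx$mu$photo, ctx$mu$incoh, ctx$mu$coh, FALSE,
    origin_mm, dir, energy_kev, as.integer(n), seed)
}
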