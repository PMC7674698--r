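test_that("realized organ volumes match reference targets within 1%", {
  ph <- ref_phantom("male")
  vol <- function(org) sum(ph$organs$volume_cc[ph$organs$organ %in% org])
  expect_equal(vol("liver"), 562, tolerance = 0.01)
  expect_equal(vol(c("lung_L", "lung_R")), 980, tolerance = 0.01)
  expect_equal(vol("heart"), 218, tolerance = 0.01)
  expect_equal(vol("stomach"), 119.4, tolerance = 0.01)
  expect_equal(vol("colon"), 149.7, tolerance = 0.01)
  expect_equal(vol("small_intestine"), 265, tolerance = 0.01)
  expect_equal(vol(c("testis_L", "testis_R")), 1.57, tolerance = 0.01)

  phf <- ref_phantom("female")
  ov <- sum(phf$organs$volume_cc[phf$organs$organ %in% c("ovary_L",
                                                         "ovary_R")])
  expect_equal(ov, 1.66, tolerance = 0.01)
})

test_that("organ masses are volume x density", {
  ph <- ref_phantom("male")
  expect_equal(organ_mass(ph, "testis"), 1.57 * 1.04, tolerance = 0.01)
  expect_equal(organ_mass(ph, "kidney"), 110, tolerance = 0.01)
  phf <- ref_phantom("female")
  expect_equal(organ_mass(phf, "ovary"), 1.66 * 1.04, tolerance = 0.01)
  expect_error(organ_mass(ph, "ovary"), "not present")
  expect_error(organ_mass(ph, "nonsense"), "not present")
})

test_that("labels partition the grid: one organ id per voxel", {
  ph <- ref_phantom("male")
  counts <- table(factor(ph$labels[ph$labels > 0], levels = ph$organs$id))
  expect_equal(as.integer(counts), ph$organs$n_vox)
  expect_equal(sum(ph$organs$n_vox), sum(ph$labels > 0))
})

test_that("anatomical relations hold: testes below bladder, right kidney
           under the liver, gonads mirror-symmetric", {
  ph <- ref_phantom("male")
  expect_lt(max(organ_z(ph, "testis_L")), min(organ_z(ph, "bladder_content")))
  expect_lt(max(organ_z(ph, "testis_R")), min(organ_z(ph, "bladder_content")))

  # right kidney superior pole abuts the liver: directly above some top
  # kidney voxel sits a liver voxel
  d <- dim(ph$labels)
  kid_id <- ph$organs$id[ph$organs$organ == "kidney_R"]
  liv_id <- ph$organs$id[ph$organs$organ == "liver"]
  idx <- which(ph$labels == kid_id)
  above <- idx + prod(d[1:2])                 # z + 1 neighbour
  above <- above[above <= prod(d)]
  expect_gt(sum(ph$labels[above] == liv_id), 0)
  # and the kidney's z range reaches into the liver's
  expect_gt(max(organ_z(ph, "kidney_R")), min(organ_z(ph, "liver")))

  # paired organs are exact mirror images
  nx <- d[1]
  mirror_lin <- function(lin) {
    ix <- (lin - 1L) %% nx + 1L
    (nx + 1L - ix) + nx * ((lin - 1L) %/% nx)
  }
  for (pair in list(c("kidney_L", "kidney_R"), c("testis_L", "testis_R"))) {
    l <- organ_voxels(ph, pair[1])
    r <- organ_voxels(ph, pair[2])
    expect_setequal(mirror_lin(l), r)
  }
  phf <- ref_phantom("female")
  expect_setequal(mirror_lin(organ_voxels(phf, "ovary_L")),
                  organ_voxels(phf, "ovary_R"))
})

test_that("mirroring swaps paired organ labels and is an involution", {
  ph <- ref_phantom("male")
  pm <- mirror_phantom(ph)
  # exact mirror pairs are invariant once sides are relabelled
  expect_setequal(organ_voxels(pm, "kidney_L"), organ_voxels(ph, "kidney_L"))
  expect_setequal(organ_voxels(pm, "testis_R"), organ_voxels(ph, "testis_R"))
  # an unpaired asymmetric organ (the liver) moves to the reflected side
  d <- dim(ph$labels); nx <- d[1]
  mirror_lin <- function(lin) {
    ix <- (lin - 1L) %% nx + 1L
    (nx + 1L - ix) + nx * ((lin - 1L) %/% nx)
  }
  expect_setequal(organ_voxels(pm, "liver"),
                  mirror_lin(organ_voxels(ph, "liver")))
  back <- mirror_phantom(pm)
  expect_identical(back$labels, ph$labels)
})

test_that("voxel-size validation: out-of-range and too-coarse grids error", {
  expect_error(build_reference_phantom("male", 0.5), "\\[1, 10\\]")
  expect_error(build_reference_phantom("male", 12), "\\[1, 10\\]")
  expect_error(build_reference_phantom("male", 8), "too coarse")
  expect_error(build_reference_phantom("female", 6), "too coarse")
})

test_that("phantom serialization round-trips bit-exactly", {
  ph <- ref_phantom("male")
  path <- file.path(tempdir(), "ph_m5")
  write_phantom(ph, path)
  ph2 <- read_phantom(path)
  expect_identical(ph2$labels, ph$labels)
  expect_equal(ph2$voxel_mm, ph$voxel_mm)
  expect_equal(ph2$organs$organ, ph$organs$organ)
  expect_equal(ph2$organs$mass_g, ph$organs$mass_g, tolerance = 1e-12)
  expect_equal(ph2$materials$kidney$density, 1.05)

  # truncated label file is rejected
  lbl <- paste0(path, ".lbl")
  raw <- readBin(lbl, "raw", n = file.info(lbl)$size)
  writeBin(raw[1:(length(raw) - 100)], lbl)
  expect_error(read_phantom(path), "does not match")
  unlink(paste0(path, c(".lbl", ".hdr.json")))
})
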