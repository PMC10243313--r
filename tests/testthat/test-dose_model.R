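# Dose-grid model and DICOM-RT reading.

test_that("RT Dose files round-trip: values to the scaling quantum, geometry exactly", {
  b <- fx_array_base()
  g2 <- read_rt_dose(b$paths$dose)
  scaling <- max(b$grid$values) / 60000
  expect_lte(max(abs(g2$values - b$grid$values)), scaling / 2 + 1e-12)
  expect_equal(g2$origin, b$grid$origin)
  expect_equal(g2$spacing, b$grid$spacing)
  expect_equal(dim(g2$values), dim(b$grid$values))
})

test_that("stored integers scale by the dose-grid scaling factor", {
  vals <- array(seq(0, 2, length.out = 3 * 3 * 2), dim = c(3, 3, 2))
  vals[] <- round(vals / 0.001) * 0.001   # representable at the quantum
  vals[1, 1, 1] <- 2.000                  # stored 2000 with scaling 0.001
  grid <- dose_grid_3d(vals, origin = c(0, 0, 0), spacing = c(1, 1, 5))
  path <- tempfile(fileext = ".dcm")
  vaudit:::write_rt_dose_file(grid, path, scaling = 0.001)
  g <- read_rt_dose(path)
  expect_identical(g$values[1, 1, 1], 2.000)
  expect_equal(g$values, vals, tolerance = 1e-12)
})

test_that("non-uniform frame offsets and oblique orientations are rejected", {
  vals <- array(1, dim = c(4, 4, 3))
  grid <- dose_grid_3d(vals, origin = c(0, 0, 0), spacing = c(1, 1, 1))
  p1 <- tempfile(fileext = ".dcm")
  vaudit:::write_rt_dose_file(grid, p1, frame_offsets = c(1, 2, 4))
  expect_error(read_rt_dose(p1), class = "vaudit_unsupported_geometry_error")
  p2 <- tempfile(fileext = ".dcm")
  th <- 5 * pi / 180
  vaudit:::write_rt_dose_file(grid, p2,
                              orientation = c(cos(th), sin(th), 0,
                                              -sin(th), cos(th), 0))
  expect_error(read_rt_dose(p2), class = "vaudit_unsupported_geometry_error")
  expect_error(read_rt_dose(tempfile()), class = "vaudit_format_error")
})

test_that("reader agrees with an independent DICOM implementation (pydicom)", {
  py <- Sys.which("python")
  expect_true(nzchar(py))  # part of the analysis environment
  dose_path <- tempfile(fileext = ".dcm")
  plan_path <- tempfile(fileext = ".dcm")
  script <- sprintf('
import numpy as np, pydicom
from pydicom.dataset import Dataset, FileDataset, FileMetaDataset
from pydicom.uid import ExplicitVRLittleEndian
arr = (np.arange(2*3*4).reshape(2,3,4) * 100).astype("uint16")
meta = FileMetaDataset()
meta.MediaStorageSOPClassUID = pydicom.uid.UID("1.2.840.10008.5.1.4.1.1.481.2")
meta.MediaStorageSOPInstanceUID = pydicom.uid.UID("1.2.3.4.5")
meta.TransferSyntaxUID = ExplicitVRLittleEndian
ds = FileDataset("x", {}, file_meta=meta, preamble=b"\\0"*128)
ds.Modality = "RTDOSE"; ds.SOPClassUID = meta.MediaStorageSOPClassUID
ds.SOPInstanceUID = meta.MediaStorageSOPInstanceUID
ds.Rows, ds.Columns, ds.NumberOfFrames = 3, 4, 2
ds.ImagePositionPatient = [-10.0, -20.0, -30.0]
ds.ImageOrientationPatient = [1,0,0,0,1,0]
ds.PixelSpacing = [2.0, 1.5]
ds.GridFrameOffsetVector = [0.0, 3.0]
ds.BitsAllocated = 16; ds.BitsStored = 16; ds.HighBit = 15
ds.PixelRepresentation = 0; ds.SamplesPerPixel = 1
ds.PhotometricInterpretation = "MONOCHROME2"
ds.DoseUnits = "GY"; ds.DoseType = "PHYSICAL"; ds.DoseSummationType = "FRACTION"
ds.DoseGridScaling = 0.001
ds.PixelData = arr.tobytes()
ds.save_as("%s", write_like_original=False)
meta2 = FileMetaDataset()
meta2.MediaStorageSOPClassUID = pydicom.uid.UID("1.2.840.10008.5.1.4.1.1.481.5")
meta2.MediaStorageSOPInstanceUID = pydicom.uid.UID("1.2.3.4.6")
meta2.TransferSyntaxUID = ExplicitVRLittleEndian
pl = FileDataset("y", {}, file_meta=meta2, preamble=b"\\0"*128)
pl.Modality = "RTPLAN"; pl.SOPClassUID = meta2.MediaStorageSOPClassUID
pl.SOPInstanceUID = meta2.MediaStorageSOPInstanceUID
fg = Dataset(); fg.NumberOfFractionsPlanned = 10
pl.FractionGroupSequence = [fg]
dr = Dataset(); dr.TargetPrescriptionDose = 20.0
pl.DoseReferenceSequence = [dr]
beam = Dataset(); cp = Dataset(); cp.IsocenterPosition = [12.5, -3.0, 40.0]
beam.ControlPointSequence = [cp]; pl.BeamSequence = [beam]
pl.save_as("%s", write_like_original=False)
', dose_path, plan_path)
  sf <- tempfile(fileext = ".py")
  writeLines(script, sf)
  expect_equal(system2(py, sf, stdout = TRUE, stderr = TRUE), character(0))

  g <- read_rt_dose(dose_path)
  expect_equal(dim(g$values), c(4L, 3L, 2L))
  expect_equal(g$origin, c(-10, -20, -30))
  expect_equal(g$spacing, c(1.5, 2, 3))   # (col, row, frame) pitch
  # stored value at frame 0, row 0, col 1 is 100 -> 0.1 Gy
  expect_equal(g$values[2, 1, 1], 0.1)
  expect_equal(g$values[1, 2, 1], 0.4)
  expect_equal(g$values[1, 1, 2], 1.2)

  p <- read_rt_plan(plan_path)
  expect_equal(p$isocenter, c(12.5, -3, 40))
  expect_equal(p$n_fractions, 10)
  expect_equal(p$prescription_dose, 20)
})

test_that("RT Plan round-trips; missing fields flagged absent; no isocenter rejected", {
  pl <- plan_info(isocenter = c(12.5, -3.0, 40.0), n_fractions = 10,
                  prescription_dose = 20)
  path <- tempfile(fileext = ".dcm")
  vaudit:::write_rt_plan_file(pl, path)
  p2 <- read_rt_plan(path)
  expect_identical(p2$isocenter, c(12.5, -3.0, 40.0))
  expect_equal(p2$n_fractions, 10)
  expect_equal(p2$prescription_dose, 20)

  pl_bare <- plan_info(isocenter = c(0, 0, 0))
  path2 <- tempfile(fileext = ".dcm")
  vaudit:::write_rt_plan_file(pl_bare, path2)
  p3 <- read_rt_plan(path2)
  expect_true(is.na(p3$prescription_dose))
  expect_true(is.na(p3$n_fractions))

  # a plan object with no beam isocenter anywhere
  body <- c(vaudit:::dcm_element(0x0008, 0x0060, "CS", "RTPLAN"),
            vaudit:::dcm_element(0x300A, 0x0002, "SH", "EMPTY"))
  path3 <- tempfile(fileext = ".dcm")
  vaudit:::dcm_write_file(path3, "1.2.840.10008.5.1.4.1.1.481.5", "1.2.3",
                          body)
  expect_error(read_rt_plan(path3), class = "vaudit_format_error")
})

test_that("extract_plane: exact on slices, linear between them, exact on linear fields", {
  vals <- array(runif(5 * 6 * 7), dim = c(5, 6, 7))
  grid <- dose_grid_3d(vals, origin = c(-2, -3, 0), spacing = c(1, 1, 2))
  # coordinate exactly on slice 3 (z = 4)
  pl <- extract_plane(grid, "axial", 4)
  expect_identical(pl$values, vals[, , 3])
  expect_equal(pl$origin, c(-2, -3))
  # midway between slices with doses 1 and 3 -> 2
  v2 <- array(0, dim = c(3, 3, 2))
  v2[, , 1] <- 1; v2[, , 2] <- 3
  g2 <- dose_grid_3d(v2, origin = c(0, 0, 0), spacing = c(1, 1, 2))
  expect_equal(extract_plane(g2, "axial", 1)$values, matrix(2, 3, 3))
  # linear field D = 0.01 z reproduced by any coronal extraction
  z <- (0:6) * 2
  v3 <- array(rep(0.01 * z, each = 5 * 6), dim = c(5, 6, 7))
  g3 <- dose_grid_3d(v3, origin = c(0, 0, 0), spacing = c(1, 1, 2))
  pl3 <- extract_plane(g3, "coronal", 2.35)
  expect_lt(max(abs(sweep(pl3$values, 2, 0.01 * z))), 1e-9)
  expect_error(extract_plane(grid, "axial", 100),
               class = "vaudit_bounds_error")
  expect_error(extract_plane(grid, "coronal", -3.001),
               class = "vaudit_bounds_error")
})

test_that("resample_plane: identity, constant conservation, exact on linear ramps", {
  vals <- matrix(runif(20 * 15), 20, 15)
  pl <- dose_grid_2d(vals, origin = c(0, 0), spacing = c(2, 2))
  expect_equal(resample_plane(pl, 2)$values, vals)
  cst <- dose_grid_2d(matrix(1.7, 10, 10), c(0, 0), c(3, 3))
  expect_true(all(abs(resample_plane(cst, 0.7)$values - 1.7) < 1e-12))
  # linear ramp: bilinear interpolation is exact
  u <- (0:19) * 2; v <- (0:14) * 2
  ramp <- outer(u, v, function(a, b) 0.3 * a + 0.1 * b + 0.5)
  plr <- dose_grid_2d(ramp, c(0, 0), c(2, 2))
  fine <- resample_plane(plr, 1)
  uf <- (0:38) * 1; vf <- (0:28) * 1
  expect_lt(max(abs(fine$values - outer(uf, vf, function(a, b) 0.3 * a + 0.1 * b + 0.5))),
            1e-9)
  expect_identical(fine$values[1, 1], ramp[1, 1])  # corner preserved
  expect_error(resample_plane(pl, 0), class = "vaudit_argument_error")
})

test_that("grids violating spacing or finiteness invariants are rejected", {
  v <- array(1, dim = c(2, 2, 2))
  expect_error(dose_grid_3d(v, c(0, 0, 0), c(1, -1, 1)),
               class = "vaudit_argument_error")
  v_bad <- v; v_bad[1, 1, 1] <- NaN
  expect_error(dose_grid_3d(v_bad, c(0, 0, 0), c(1, 1, 1)),
               class = "vaudit_argument_error")
  v_neg <- v; v_neg[2, 2, 2] <- -0.1
  expect_error(dose_grid_3d(v_neg, c(0, 0, 0), c(1, 1, 1)),
               class = "vaudit_argument_error")
  expect_error(dose_grid_2d(matrix(Inf, 2, 2), c(0, 0), c(1, 1)),
               class = "vaudit_argument_error")
  expect_error(plan_info(c(0, 0, 0), n_fractions = 0),
               class = "vaudit_argument_error")
})
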