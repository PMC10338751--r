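test_that("RT Ion Plan write/read round-trips spot data at declared precision", {
  for (seed in c(4, 27)) {
    plan <- generate_plan(n_fields = 2, layers_per_field = 3,
                          spots_per_layer = 7, seed = seed)
    path <- withr::local_tempfile(fileext = ".dcm")
    write_plan(plan, path, format = "rtion-dicom")
    back <- read_plan(path, format = "rtion-dicom")
    expect_equal(nrow(back), nrow(plan))
    expect_equal(back$field_id, plan$field_id)
    expect_equal(back$layer_index, plan$layer_index)
    expect_equal(back$energy_MeV, plan$energy_MeV, tolerance = 1e-6)
    expect_lt(max(abs(back$x_mm - plan$x_mm)), 1e-3)
    expect_lt(max(abs(back$y_mm - plan$y_mm)), 1e-3)
    expect_lt(max(abs(back$mu - plan$mu)), 1e-6)
  }
})

test_that("a plan whose meterset weights are all zero is a format error", {
  plan <- tiny_plan(n_layers = 2, n_spots = 3)
  plan$mu <- 0
  path <- withr::local_tempfile(fileext = ".dcm")
  write_plan(plan, path, format = "rtion-dicom")
  expect_qa_error(read_plan(path, format = "rtion-dicom"),
                  "qa_format_error", "zero|no scan spots")
})

test_that("non-RT-Ion and non-explicit-LE inputs are rejected", {
  path <- withr::local_tempfile(fileext = ".dcm")
  writeBin(as.raw(rep(0, 200)), path)
  expect_qa_error(read_plan(path, format = "rtion-dicom"),
                  "qa_format_error", "Part-10")
})

test_that("an independent DICOM decoder reads our files back verbatim", {
  py <- Sys.which("python")
  skip_if(py == "", "python not on PATH")
  plan <- generate_plan(n_fields = 1, layers_per_field = 2,
                        spots_per_layer = 5, seed = 55)
  path <- withr::local_tempfile(fileext = ".dcm")
  write_plan(plan, path, format = "rtion-dicom")
  script <- withr::local_tempfile(fileext = ".py")
  writeLines(c(
    "import sys, pydicom",
    "ds = pydicom.dcmread(sys.argv[1])",
    "assert ds.SOPClassUID == '1.2.840.10008.5.1.4.1.1.481.8'",
    "bm = float(ds.FractionGroupSequence[0].ReferencedBeamSequence[0].BeamMeterset)",
    "beam = ds.IonBeamSequence[0]",
    "assert beam.ScanMode == 'MODULATED'",
    "scale = bm / float(beam.FinalCumulativeMetersetWeight)",
    "for cp in beam.IonControlPointSequence:",
    "    w = [float(v) for v in cp.ScanSpotMetersetWeights]",
    "    if sum(w) == 0: continue",
    "    pos = [float(v) for v in cp.ScanSpotPositionMap]",
    "    for k in range(len(w)):",
    "        print('%r %r %r %r' % (float(cp.NominalBeamEnergy),",
    "              pos[2*k], pos[2*k+1], w[k]*scale))"
  ), script)
  out <- system2(py, c(script, path), stdout = TRUE)
  vals <- do.call(rbind, lapply(strsplit(out, " +"), as.numeric))
  expect_equal(nrow(vals), nrow(plan))
  expect_equal(vals[, 1], plan$energy_MeV, tolerance = 1e-9)
  expect_lt(max(abs(vals[, 2] - plan$x_mm)), 1e-3)
  expect_lt(max(abs(vals[, 3] - plan$y_mm)), 1e-3)
  expect_lt(max(abs(vals[, 4] - plan$mu)), 1e-6)
})

test_that("our reader decodes a plan written by an independent encoder", {
  py <- Sys.which("python")
  skip_if(py == "", "python not on PATH")
  path <- withr::local_tempfile(fileext = ".dcm")
  script <- withr::local_tempfile(fileext = ".py")
  # pydicom writes undefined-length sequences by default when asked;
  # here it emits defined lengths -- either way our parser must cope
  writeLines(c(
    "import sys, pydicom",
    "from pydicom.dataset import Dataset, FileMetaDataset",
    "from pydicom.uid import ExplicitVRLittleEndian, generate_uid",
    "meta = FileMetaDataset()",
    "meta.MediaStorageSOPClassUID = '1.2.840.10008.5.1.4.1.1.481.8'",
    "meta.MediaStorageSOPInstanceUID = generate_uid()",
    "meta.TransferSyntaxUID = ExplicitVRLittleEndian",
    "ds = Dataset()",
    "ds.SOPClassUID = meta.MediaStorageSOPClassUID",
    "ds.SOPInstanceUID = meta.MediaStorageSOPInstanceUID",
    "ds.Modality = 'RTPLAN'",
    "fg = Dataset(); rb = Dataset()",
    "rb.ReferencedBeamNumber = 1; rb.BeamMeterset = '0.06'",
    "fg.ReferencedBeamSequence = [rb]",
    "ds.FractionGroupSequence = [fg]",
    "beam = Dataset()",
    "beam.BeamNumber = 1; beam.BeamName = 'PA1'; beam.ScanMode = 'MODULATED'",
    "beam.FinalCumulativeMetersetWeight = '1.0'",
    "cp0 = Dataset()",
    "cp0.ControlPointIndex = 0; cp0.NominalBeamEnergy = '120.5'",
    "cp0.GantryAngle = '180.0'; cp0.CumulativeMetersetWeight = '0.0'",
    "cp0.NumberOfScanSpotPositions = 2",
    "cp0.ScanSpotPositionMap = [1.5, -2.5, 3.0, 4.0]",
    "cp0.ScanSpotMetersetWeights = [0.25, 0.75]",
    "cp1 = Dataset()",
    "cp1.ControlPointIndex = 1; cp1.NominalBeamEnergy = '120.5'",
    "cp1.CumulativeMetersetWeight = '1.0'",
    "cp1.NumberOfScanSpotPositions = 2",
    "cp1.ScanSpotPositionMap = [1.5, -2.5, 3.0, 4.0]",
    "cp1.ScanSpotMetersetWeights = [0.0, 0.0]",
    "beam.IonControlPointSequence = [cp0, cp1]",
    "ds.IonBeamSequence = [beam]",
    "fds = pydicom.dataset.FileDataset(sys.argv[1], ds, file_meta=meta,",
    "                                  preamble=b'\\x00'*128)",
    "fds.save_as(sys.argv[1], enforce_file_format=True)"
  ), script)
  res <- system2(py, c(script, path), stdout = TRUE, stderr = TRUE)
  skip_if(!file.exists(path) || file.info(path)$size == 0,
          paste("pydicom writer failed:", paste(res, collapse = " ")))
  plan <- read_plan(path, format = "rtion-dicom")
  expect_equal(nrow(plan), 2)
  expect_equal(plan$field_id, c("PA1", "PA1"))
  expect_equal(plan$energy_MeV, c(120.5, 120.5))
  expect_equal(plan$gantry_angle_deg, c(180, 180))
  expect_equal(plan$x_mm, c(1.5, 3.0), tolerance = 1e-6)
  expect_equal(plan$y_mm, c(-2.5, 4.0), tolerance = 1e-6)
  # weights 0.25/0.75 of a 0.06 MU beam with final cumulative weight 1
  expect_equal(plan$mu, c(0.015, 0.045), tolerance = 1e-8)
})
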