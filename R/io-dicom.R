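# RT Ion Plan (SOP class 1.2.840.10008.5.1.4.1.1.481.8) <-> plan tibble.
#
# Each field becomes one ion beam with MODULATED scan mode. Every energy
# layer is a pair of ion control points: the even control point carries
# the nominal energy, the scan-spot position map (x1 y1 x2 y2 ..., mm at
# isocenter) and the per-spot meterset weight increments; the odd control
# point closes the layer with zero weights. Absolute spot MU relates to
# weights through
#
#   MU_spot = weight * BeamMeterset / FinalCumulativeMetersetWeight
#
# The writer uses weight == MU (so BeamMeterset == FinalCumulative-
# MetersetWeight == total field MU); the reader applies the general rule,
# so plans from any compliant source convert to absolute MU at read time.

el <- dicom_element  # local alias, R/dicom.R

write_plan_dicom <- function(plan, path, comment = NULL) {
  plan <- order_plan(plan)
  fields <- split(plan, plan$field_id)
  fields <- fields[unique(plan$field_id)]

  ref_beams <- list()
  ion_beams <- list()
  for (bi in seq_along(fields)) {
    f <- fields[[bi]]
    total_mu <- sum(f$mu)
    ref_beams[[bi]] <- list(
      el(0x300A, 0x0086, "DS", total_mu),        # BeamMeterset
      el(0x300C, 0x0006, "IS", bi)               # ReferencedBeamNumber
    )
    cps <- list()
    cum <- 0
    layer_ids <- unique(f$layer_index)
    for (k in seq_along(layer_ids)) {
      layer <- f[f$layer_index == layer_ids[k], ]
      nsp <- nrow(layer)
      pos_map <- as.vector(rbind(layer$x_mm, layer$y_mm))
      open_cp <- list(
        el(0x300A, 0x0112, "IS", 2 * k - 2),                 # ControlPointIndex
        el(0x300A, 0x0114, "DS", layer$energy_MeV[1]),       # NominalBeamEnergy
        el(0x300A, 0x0134, "DS", cum),                       # CumulativeMetersetWeight
        el(0x300A, 0x0392, "IS", nsp),                       # NumberOfScanSpotPositions
        el(0x300A, 0x0394, "FL", pos_map),                   # ScanSpotPositionMap
        el(0x300A, 0x0396, "FL", layer$mu)                   # ScanSpotMetersetWeights
      )
      if (k == 1) {
        open_cp <- append(open_cp, list(el(0x300A, 0x011E, "DS", f$gantry_angle_deg[1])),
                          after = 2)
      }
      cum <- cum + sum(layer$mu)
      close_cp <- list(
        el(0x300A, 0x0112, "IS", 2 * k - 1),
        el(0x300A, 0x0114, "DS", layer$energy_MeV[1]),
        el(0x300A, 0x0134, "DS", cum),
        el(0x300A, 0x0392, "IS", nsp),
        el(0x300A, 0x0394, "FL", pos_map),
        el(0x300A, 0x0396, "FL", rep(0, nsp))
      )
      cps[[2 * k - 1]] <- open_cp
      cps[[2 * k]] <- close_cp
    }
    ion_beams[[bi]] <- list(
      el(0x300A, 0x00C0, "IS", bi),                          # BeamNumber
      el(0x300A, 0x00C2, "LO", f$field_id[1]),               # BeamName
      el(0x300A, 0x00C6, "CS", "PROTON"),                    # RadiationType
      el(0x300A, 0x010E, "DS", cum),                         # FinalCumulativeMetersetWeight
      el(0x300A, 0x0110, "IS", length(cps)),                 # NumberOfControlPoints
      el(0x300A, 0x0308, "CS", "MODULATED"),                 # ScanMode
      el(0x300A, 0x03A8, "SQ", cps)                          # IonControlPointSequence
    )
  }

  sop_uid <- new_uid()
  dataset <- list(
    el(0x0008, 0x0016, "UI", RTION_SOP_CLASS),
    el(0x0008, 0x0018, "UI", sop_uid),
    el(0x0008, 0x0060, "CS", "RTPLAN"),
    el(0x300A, 0x0002, "SH", "spotqa plan"),
    el(0x300A, 0x0004, "ST", if (is.null(comment)) "" else comment),  # RTPlanDescription
    el(0x300A, 0x0070, "SQ", list(list(
      el(0x300A, 0x0071, "IS", 1),                           # FractionGroupNumber
      el(0x300A, 0x0078, "IS", 1),                           # NumberOfFractionsPlanned
      el(0x300A, 0x0080, "IS", length(fields)),              # NumberOfBeams
      el(0x300C, 0x0004, "SQ", ref_beams)                    # ReferencedBeamSequence
    ))),
    el(0x300A, 0x03A2, "SQ", ion_beams)                      # IonBeamSequence
  )
  writeBin(dicom_file_raw(dataset, sop_uid), path)
  invisible(path)
}

get_el <- function(ds, key, beam = NULL, default = NULL) {
  v <- ds[[key]]
  if (is.null(v)) {
    if (!is.null(default)) return(default)
    qa_abort(sprintf("missing DICOM attribute (%s)%s", key,
                     if (is.null(beam)) "" else paste0(" in beam ", beam)),
             "qa_format_error")
  }
  v
}

read_plan_dicom <- function(path) {
  ds <- read_dicom_file(path)
  sop <- get_el(ds, "0008,0016")
  if (!identical(sop, RTION_SOP_CLASS)) {
    qa_abort(paste0("not an RT Ion Plan (SOP class ", sop, ")"), "qa_format_error")
  }
  # beam number -> beam meterset from the fraction group
  metersets <- list()
  for (fg in get_el(ds, "300A,0070", default = list())) {
    for (rb in fg[["300C,0004"]] %||% list()) {
      bn <- as.character(rb[["300C,0006"]])
      metersets[[bn]] <- rb[["300A,0086"]]
    }
  }
  beams <- get_el(ds, "300A,03A2")
  out <- list()
  for (beam in beams) {
    bn <- get_el(beam, "300A,00C0")
    bname <- beam[["300A,00C2"]] %||% sprintf("B%02d", bn)
    scan_mode <- beam[["300A,0308"]] %||% "NONE"
    if (!identical(scan_mode, "MODULATED")) {
      qa_abort(sprintf("beam %s: scan mode %s is not MODULATED", bname, scan_mode),
               "qa_format_error")
    }
    final_cum <- get_el(beam, "300A,010E", bname)
    if (!is.numeric(final_cum) || final_cum <= 0) {
      qa_abort(sprintf("beam %s: final cumulative meterset weight is zero", bname),
               "qa_format_error")
    }
    bm <- metersets[[as.character(bn)]]
    if (is.null(bm)) {
      qa_abort(sprintf("beam %s: no referenced beam meterset", bname), "qa_format_error")
    }
    mu_per_weight <- bm / final_cum
    cps <- get_el(beam, "300A,03A8", bname)
    gantry <- 0
    layer <- 0
    for (cp in cps) {
      if (!is.null(cp[["300A,011E"]])) gantry <- cp[["300A,011E"]]
      w <- cp[["300A,0396"]]
      if (is.null(w) || sum(w) == 0) next  # closing control point
      pos <- get_el(cp, "300A,0394", bname)
      energy <- get_el(cp, "300A,0114", bname)
      nsp <- length(w)
      if (length(pos) != 2 * nsp) {
        qa_abort(sprintf("beam %s: scan spot position map length %d does not match %d weights",
                         bname, length(pos), nsp), "qa_format_error")
      }
      out[[length(out) + 1]] <- tibble(
        field_id = as.character(bname),
        gantry_angle_deg = as.numeric(gantry),
        layer_index = layer,
        energy_MeV = as.numeric(energy),
        spot_index = seq_len(nsp) - 1,
        x_mm = pos[seq(1, 2 * nsp, by = 2)],
        y_mm = pos[seq(2, 2 * nsp, by = 2)],
        mu = w * mu_per_weight
      )
      layer <- layer + 1
    }
    if (layer == 0) {
      qa_abort(sprintf("beam %s: no scan spots", bname), "qa_format_error")
    }
  }
  order_plan(list_rbind(out))
}
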