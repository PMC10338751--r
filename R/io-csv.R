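# CSV dialects for plans, delivery logs and baselines.
#
# The native record-and-verify log format is proprietary; this package
# defines an open CSV dialect carrying everything the QA needs (per-spot
# MU, position, size plus session metadata). All text I/O is
# locale-independent (dot decimal separator, comma field separator, "\n" or
# "\r\n" accepted on read). Lines starting with '#' are comments and may
# carry provenance notes. Headers must match the dialect version exactly.
#
#   plan v1:     field_id,gantry_angle_deg,layer_index,energy_MeV,spot_index,x_mm,y_mm,mu
#   log v1:      session_id,room,date,field_id,gantry_angle_deg,layer_index,energy_MeV,spot_index,x_mm,y_mm,mu,sigma_x_mm,sigma_y_mm
#   baseline v1: energy_MeV,gantry_angle_deg,sigma_x_mm,sigma_y_mm

LOG_CHR_COLS <- c("session_id", "room", "date", "field_id")
PLAN_CHR_COLS <- "field_id"

# strict reader: exact header, numeric coercion with line-numbered errors
read_strict_csv <- function(path, cols, chr_cols = character(0)) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) qa_abort(paste0("empty file: ", path), "qa_format_error")
  header <- lines[[1]]
  expected <- paste(cols, collapse = ",")
  if (!identical(header, expected)) {
    qa_abort(sprintf("header mismatch in %s\n  expected: %s\n  found:    %s",
                     path, expected, header), "qa_format_error")
  }
  body <- lines[-1]
  body_no <- line_no[-1]
  if (length(body) == 0) {
    out <- lapply(cols, function(cl) if (cl %in% chr_cols) character(0) else numeric(0))
    return(as_tibble(setNames(out, cols)))
  }
  cells <- strsplit(body, ",", fixed = TRUE)
  nfld <- lengths(cells)
  if (any(nfld != length(cols))) {
    bad <- which(nfld != length(cols))[1]
    qa_abort(sprintf("line %d of %s: expected %d fields, found %d",
                     body_no[bad], path, length(cols), nfld[bad]), "qa_format_error")
  }
  mat <- do.call(rbind, cells)
  out <- setNames(vector("list", length(cols)), cols)
  for (j in seq_along(cols)) {
    v <- trimws(mat[, j])
    if (cols[j] %in% chr_cols) {
      out[[j]] <- v
    } else {
      num <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(num) & !(v %in% c("NA", "")))
      if (length(bad) > 0) {
        qa_abort(sprintf("line %d of %s: non-numeric value '%s' in column %s",
                         body_no[bad[1]], path, v[bad[1]], cols[j]), "qa_format_error")
      }
      num[v == ""] <- NA_real_
      out[[j]] <- num
    }
  }
  as_tibble(out)
}

# shortest decimal string that reads back to exactly the same double
fmt_shortest <- function(x) {
  out <- sprintf("%.15g", x)
  for (d in c(16L, 17L)) {
    redo <- !is.na(x) & suppressWarnings(as.numeric(out)) != x
    if (!any(redo)) break
    out[redo] <- sprintf(paste0("%.", d, "g"), x[redo])
  }
  out
}

# serialize a spot table in dialect column order; positions to 0.001 mm,
# energies to 0.1 MeV, free columns at full double precision
write_dialect_csv <- function(tab, path, comment = NULL) {
  cols <- names(tab)
  txt <- lapply(cols, function(cl) {
    v <- tab[[cl]]
    if (is.character(v)) return(v)
    out <- if (cl %in% c("x_mm", "y_mm")) sprintf("%.3f", v)
    else if (cl == "energy_MeV") sprintf("%.1f", v)
    else if (cl %in% c("layer_index", "spot_index")) sprintf("%d", as.integer(v))
    else fmt_shortest(v)
    out[is.na(v)] <- ""
    out
  })
  rows <- do.call(paste, c(txt, sep = ","))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writer <- function(s) writeLines(s, con, sep = "\n")
  if (!is.null(comment)) writer(paste0("# ", comment))
  writer(paste(cols, collapse = ","))
  if (length(rows) > 0) writer(rows)
  invisible(path)
}

order_plan <- function(plan) {
  dplyr::arrange(plan, .data$field_id, .data$layer_index, .data$spot_index)
}

check_layer_structure <- function(tab, path = "<plan>") {
  grp <- split(tab, tab$field_id)
  for (f in grp) {
    li <- unique(f$layer_index)
    if (!identical(sort(li), as.numeric(seq_along(li) - 1))) {
      qa_abort(sprintf("%s: field %s layer_index not contiguous from 0",
                       path, f$field_id[1]), "qa_format_error")
    }
    by_layer <- split(f$energy_MeV, f$layer_index)
    if (any(vapply(by_layer, function(e) length(unique(e)) != 1, logical(1)))) {
      qa_abort(sprintf("%s: field %s has inconsistent energy within a layer",
                       path, f$field_id[1]), "qa_format_error")
    }
  }
  invisible(tab)
}

#' Read a planned spot map
#'
#' @param path File path.
#' @param format `"csv"` for the plan CSV dialect, or `"rtion-dicom"` for a
#'   DICOM RT Ion Plan. For DICOM, spot meterset weights are converted to
#'   absolute MU at read time (weight x beam meterset / final cumulative
#'   meterset weight) so all internal comparisons are in MU.
#' @return A plan tibble (one row per spot; see package docs for columns).
#' @export
read_plan <- function(path, format = c("csv", "rtion-dicom")) {
  format <- match.arg(format)
  if (!file.exists(path)) qa_abort(paste0("no such file: ", path), "qa_io_error")
  if (format == "rtion-dicom") return(read_plan_dicom(path))
  tab <- read_strict_csv(path, PLAN_COLS, PLAN_CHR_COLS)
  if (nrow(tab) == 0) qa_abort(paste0("plan has no spots: ", path), "qa_format_error")
  check_layer_structure(tab, path)
  order_plan(tab)
}

#' Write a planned spot map
#'
#' @param plan Plan tibble.
#' @inheritParams read_plan
#' @param comment Optional provenance note embedded as a `#` comment (CSV)
#'   or in the plan description (DICOM).
#' @export
write_plan <- function(plan, path, format = c("csv", "rtion-dicom"),
                       comment = NULL) {
  format <- match.arg(format)
  check_plan_frame(plan)
  plan <- order_plan(as_tibble(plan))
  if (format == "rtion-dicom") return(write_plan_dicom(plan, path, comment))
  write_dialect_csv(plan[PLAN_COLS], path, comment)
}

#' Read a delivery log
#'
#' Parses the delivery-log CSV dialect into a session tibble. The room
#' must be one of `G1`, `G2`, `FX-STD`, `FX-MICRO`; rows must be grouped
#' by field with layer indices non-decreasing in file order. Rows are
#' never silently dropped: every input row becomes a spot or an error.
#'
#' @param path File path.
#' @return A session tibble (one row per delivered spot, in file order).
#' @export
read_delivery_log <- function(path) {
  if (!file.exists(path)) qa_abort(paste0("no such file: ", path), "qa_io_error")
  tab <- read_strict_csv(path, LOG_COLS, LOG_CHR_COLS)
  if (nrow(tab) == 0) qa_abort(paste0("log has no spots: ", path), "qa_format_error")
  bad_room <- which(!(tab$room %in% QA_ROOMS))
  if (length(bad_room) > 0) {
    qa_abort(sprintf("line %d of %s: unknown room '%s' (expected %s)",
                     bad_room[1] + 1, path, tab$room[bad_room[1]],
                     paste(QA_ROOMS, collapse = "/")), "qa_format_error")
  }
  for (f in split(seq_len(nrow(tab)), tab$field_id)) {
    li <- tab$layer_index[f]
    if (any(diff(li) < 0)) {
      qa_abort(sprintf("line %d of %s: layer_index out of order in field %s",
                       f[which(diff(li) < 0)[1] + 1] + 1, path, tab$field_id[f[1]]),
               "qa_format_error")
    }
  }
  check_layer_structure(tab, path)
  tab
}

#' Write a delivery log
#'
#' @param session Session tibble.
#' @param path File path.
#' @param comment Optional `#` provenance comment.
#' @export
write_delivery_log <- function(session, path, comment = NULL) {
  check_log_frame(session)
  write_dialect_csv(as_tibble(session)[LOG_COLS], path, comment)
}
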