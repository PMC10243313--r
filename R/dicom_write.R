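# Minimal DICOM part-10 writer (explicit VR little endian) for RT Dose and
# RT Plan objects. Lives on the synthesis side of the package so that the
# reader in dicom_read.R is exercised against an independent encoder in the
# round-trip tests. Output is fully deterministic: UIDs derive from the
# scenario seed and no timestamps are embedded.

.w16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
.w32 <- function(x) {
  x <- as.numeric(x)
  lo <- x %% 65536; hi <- x %/% 65536
  unlist(lapply(seq_along(x), function(i) c(.w16(lo[i]), .w16(hi[i]))))
}

.pad_even <- function(bytes, pad = as.raw(0)) {
  if (length(bytes) %% 2 == 1) c(bytes, pad) else bytes
}

.dcm_format_ds <- function(x) {
  paste(vapply(x, function(v) formatC(v, digits = 10, format = "g"), ""),
        collapse = "\\")
}

# Encode one data element (explicit VR little endian).
dcm_element <- function(group, element, vr, value) {
  payload <- switch(vr,
    UI = .pad_even(charToRaw(paste(value, collapse = "\\")), as.raw(0)),
    CS = , SH = , LO = , ST = , LT = , PN = , DA = , TM = ,
    AS = .pad_even(charToRaw(paste(value, collapse = "\\")), charToRaw(" ")),
    DS = .pad_even(charToRaw(.dcm_format_ds(value)), charToRaw(" ")),
    IS = .pad_even(charToRaw(paste(as.integer(value), collapse = "\\")),
                   charToRaw(" ")),
    US = .w16(value),
    UL = .w32(value),
    AT = .w16(value),
    FL = writeBin(as.numeric(value), raw(), size = 4, endian = "little"),
    FD = writeBin(as.numeric(value), raw(), size = 8, endian = "little"),
    OW = value,
    OB = .pad_even(value, as.raw(0)),
    SQ = {
      items <- lapply(value, function(item_bytes) {
        c(.w16(0xFFFE), .w16(0xE000), .w32(length(item_bytes)), item_bytes)
      })
      do.call(c, items)
    },
    stop_argument(sprintf("unsupported VR for writing: %s", vr))
  )
  head_ <- c(.w16(group), .w16(element), charToRaw(vr))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    c(head_, as.raw(c(0, 0)), .w32(length(payload)), payload)
  } else {
    if (length(payload) > 65534) stop_argument("element too long for short VR")
    c(head_, .w16(length(payload)), payload)
  }
}

# Concatenate already-encoded elements into a sequence item body.
dcm_item <- function(...) do.call(c, list(...))

.vaudit_uid_root <- "1.2.826.0.1.3680043.8.498"

dcm_uid <- function(seed, k) sprintf("%s.%d.%d", .vaudit_uid_root, as.integer(seed), k)

# Assemble and write a part-10 file from encoded dataset elements.
dcm_write_file <- function(path, sop_class_uid, sop_instance_uid, body) {
  meta <- c(
    dcm_element(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
    dcm_element(0x0002, 0x0002, "UI", sop_class_uid),
    dcm_element(0x0002, 0x0003, "UI", sop_instance_uid),
    dcm_element(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1"),
    dcm_element(0x0002, 0x0012, "UI", paste0(.vaudit_uid_root, ".1"))
  )
  out <- c(rep(as.raw(0), 128), charToRaw("DICM"),
           dcm_element(0x0002, 0x0000, "UL", length(meta)), meta, body)
  writeBin(out, path)
  invisible(path)
}

# Write a dose_grid3 as an RT Dose object. `scaling` defaults to spanning the
# grid maximum over most of the 16-bit range; `frame_offsets` can be
# overridden (e.g. deliberately non-uniform) for reader-contract tests.
write_rt_dose_file <- function(grid, path, seed = 0, scaling = NULL,
                               frame_offsets = NULL,
                               orientation = c(1, 0, 0, 0, 1, 0)) {
  d <- dim(grid$values)
  if (is.null(scaling)) {
    mx <- max(grid$values)
    scaling <- if (mx > 0) mx / 60000 else 1e-5
  }
  stored <- as.integer(round(grid$values / scaling))
  if (max(stored) > 65535) stop_argument("dose scaling overflows 16-bit storage")
  if (is.null(frame_offsets))
    frame_offsets <- (seq_len(d[3]) - 1) * grid$spacing[3]
  # values[i, j, k]: i = x/column, j = y/row, k = z/frame; DICOM wants
  # column-fastest within each row, row within frame — exactly R's layout.
  pix <- writeBin(stored, raw(), size = 2, endian = "little")
  body <- c(
    dcm_element(0x0008, 0x0016, "UI", "1.2.840.10008.5.1.4.1.1.481.2"),
    dcm_element(0x0008, 0x0018, "UI", dcm_uid(seed, 2)),
    dcm_element(0x0008, 0x0060, "CS", "RTDOSE"),
    dcm_element(0x0020, 0x000D, "UI", dcm_uid(seed, 10)),
    dcm_element(0x0020, 0x000E, "UI", dcm_uid(seed, 11)),
    dcm_element(0x0020, 0x0032, "DS", grid$origin),
    dcm_element(0x0020, 0x0037, "DS", orientation),
    dcm_element(0x0028, 0x0002, "US", 1),
    dcm_element(0x0028, 0x0004, "CS", "MONOCHROME2"),
    dcm_element(0x0028, 0x0008, "IS", d[3]),
    dcm_element(0x0028, 0x0009, "AT", c(0x3004, 0x000C)),
    dcm_element(0x0028, 0x0010, "US", d[2]),
    dcm_element(0x0028, 0x0011, "US", d[1]),
    dcm_element(0x0028, 0x0030, "DS", c(grid$spacing[2], grid$spacing[1])),
    dcm_element(0x0028, 0x0100, "US", 16),
    dcm_element(0x0028, 0x0101, "US", 16),
    dcm_element(0x0028, 0x0102, "US", 15),
    dcm_element(0x0028, 0x0103, "US", 0),
    dcm_element(0x3004, 0x0002, "CS", "GY"),
    dcm_element(0x3004, 0x0004, "CS", "PHYSICAL"),
    dcm_element(0x3004, 0x000A, "CS", "FRACTION"),
    dcm_element(0x3004, 0x000C, "DS", frame_offsets),
    dcm_element(0x3004, 0x000E, "DS", scaling),
    dcm_element(0x7FE0, 0x0010, "OW", pix)
  )
  dcm_write_file(path, "1.2.840.10008.5.1.4.1.1.481.2", dcm_uid(seed, 2), body)
}

# Write a plan_info as a minimal RT Plan object (fraction group, dose
# reference with the target prescription, one beam with the isocenter on its
# first control point).
write_rt_plan_file <- function(plan, path, seed = 0) {
  cp_item <- dcm_item(dcm_element(0x300A, 0x012C, "DS", plan$isocenter))
  beam_item <- dcm_item(
    dcm_element(0x300A, 0x00B2, "SH",
                if (is.na(plan$machine)) "SYNTH" else plan$machine),
    dcm_element(0x300A, 0x0111, "SQ", list(cp_item))
  )
  body <- c(
    dcm_element(0x0008, 0x0016, "UI", "1.2.840.10008.5.1.4.1.1.481.5"),
    dcm_element(0x0008, 0x0018, "UI", dcm_uid(seed, 5)),
    dcm_element(0x0008, 0x0060, "CS", "RTPLAN"),
    dcm_element(0x0020, 0x000D, "UI", dcm_uid(seed, 10)),
    dcm_element(0x0020, 0x000E, "UI", dcm_uid(seed, 12)),
    dcm_element(0x300A, 0x0002, "SH", "VAUDIT"),
    if (!is.na(plan$prescription_dose)) {
      dcm_element(0x300A, 0x0010, "SQ", list(
        dcm_item(dcm_element(0x300A, 0x0026, "DS", plan$prescription_dose))
      ))
    } else raw(0),
    if (!is.na(plan$n_fractions)) {
      dcm_element(0x300A, 0x0070, "SQ", list(
        dcm_item(dcm_element(0x300A, 0x0078, "IS", plan$n_fractions))
      ))
    } else raw(0),
    dcm_element(0x300A, 0x00B0, "SQ", list(beam_item))
  )
  dcm_write_file(path, "1.2.840.10008.5.1.4.1.1.481.5", dcm_uid(seed, 5), body)
}
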