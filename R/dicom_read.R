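# Minimal DICOM part-10 reader covering RT Dose and RT Plan objects.
#
# Supports explicit and implicit VR little endian transfer syntaxes and
# nested sequences (defined and undefined lengths). This is deliberately a
# small, audited subset of DICOM: enough to recover dose-grid geometry,
# scaled pixel data and plan-level metadata from standards-conformant files.

# VR dictionary for the tags this package interprets (needed for implicit VR
# and for typed value decoding).
.dcm_dict <- c(
  "00020002" = "UI", "00020003" = "UI", "00020010" = "UI", "00020012" = "UI",
  "00080016" = "UI", "00080018" = "UI", "00080060" = "CS", "00081090" = "LO",
  "0020000D" = "UI", "0020000E" = "UI",
  "00200032" = "DS", "00200037" = "DS",
  "00280002" = "US", "00280004" = "CS", "00280008" = "IS", "00280009" = "AT",
  "00280010" = "US", "00280011" = "US", "00280030" = "DS",
  "00280100" = "US", "00280101" = "US", "00280102" = "US", "00280103" = "US",
  "30040002" = "CS", "30040004" = "CS", "3004000A" = "CS",
  "3004000C" = "DS", "3004000E" = "DS",
  "300A0002" = "SH", "300A0010" = "SQ", "300A0026" = "DS",
  "300A0070" = "SQ", "300A0078" = "IS", "300A00B0" = "SQ", "300A00B2" = "SH",
  "300A0111" = "SQ", "300A012C" = "DS",
  "7FE00010" = "OW"
)

.le_uint <- function(bytes) sum(as.numeric(bytes) * 256^(seq_along(bytes) - 1))

.dcm_decode <- function(vr, bytes) {
  n <- length(bytes)
  switch(vr,
    US = , AT = readBin(bytes, "integer", n = n / 2, size = 2, signed = FALSE,
                        endian = "little"),
    UL = readBin(bytes, "integer", n = n / 4, size = 4, endian = "little"),
    SS = readBin(bytes, "integer", n = n / 2, size = 2, signed = TRUE,
                 endian = "little"),
    SL = readBin(bytes, "integer", n = n / 4, size = 4, endian = "little"),
    FL = readBin(bytes, "double", n = n / 4, size = 4, endian = "little"),
    FD = readBin(bytes, "double", n = n / 8, size = 8, endian = "little"),
    DS = , IS = {
      s <- rawToChar(bytes)
      as.numeric(strsplit(trimws(s), "\\", fixed = TRUE)[[1]])
    },
    UI = , CS = , SH = , LO = , LT = , ST = , PN = , DA = , TM = , AS = {
      s <- rawToChar(bytes[bytes != as.raw(0)])
      trimws(s)
    },
    bytes  # OW/OB/UN and anything else: raw payload
  )
}

# Parse a dataset from `raw` starting at `pos` (1-based), until `end`
# (exclusive) or until `stop_tag` is met. Returns list(elements, pos).
.dcm_parse <- function(raw, pos, end, explicit, stop_tag = NULL) {
  out <- list()
  while (pos + 7 <= end) {
    group <- .le_uint(raw[pos:(pos + 1)])
    elem <- .le_uint(raw[(pos + 2):(pos + 3)])
    tag <- sprintf("%04X%04X", group, elem)
    pos <- pos + 4
    if (!is.null(stop_tag) && tag == stop_tag) {
      pos <- pos + 4  # skip the delimiter's length field
      return(list(elements = out, pos = pos))
    }
    if (group == 0xFFFE) {  # item/delimiter outside expected context: skip
      len <- .le_uint(raw[pos:(pos + 3)]); pos <- pos + 4
      if (len != 0xFFFFFFFF) pos <- pos + len
      next
    }
    exp_here <- explicit || group == 2L
    if (exp_here) {
      vr <- rawToChar(raw[pos:(pos + 1)]); pos <- pos + 2
      if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
        pos <- pos + 2
        len <- .le_uint(raw[pos:(pos + 3)]); pos <- pos + 4
      } else {
        len <- .le_uint(raw[pos:(pos + 1)]); pos <- pos + 2
      }
    } else {
      vr <- unname(.dcm_dict[tag])
      len <- .le_uint(raw[pos:(pos + 3)]); pos <- pos + 4
      if (is.na(vr)) vr <- if (len == 0xFFFFFFFF) "SQ" else "UN"
    }
    if (vr == "SQ") {
      items <- list()
      if (len == 0xFFFFFFFF) {
        repeat {
          ig <- .le_uint(raw[pos:(pos + 1)]); ie <- .le_uint(raw[(pos + 2):(pos + 3)])
          itag <- sprintf("%04X%04X", ig, ie); pos <- pos + 4
          ilen <- .le_uint(raw[pos:(pos + 3)]); pos <- pos + 4
          if (itag == "FFFEE0DD") break
          if (itag != "FFFEE000") stop_format("malformed sequence item tag")
          if (ilen == 0xFFFFFFFF) {
            r <- .dcm_parse(raw, pos, end, explicit, stop_tag = "FFFEE00D")
          } else {
            r <- .dcm_parse(raw, pos, pos + ilen - 1, explicit)
          }
          items[[length(items) + 1L]] <- r$elements
          pos <- r$pos
        }
      } else {
        sq_end <- pos + len - 1
        while (pos <= sq_end - 7) {
          ig <- .le_uint(raw[pos:(pos + 1)]); ie <- .le_uint(raw[(pos + 2):(pos + 3)])
          itag <- sprintf("%04X%04X", ig, ie); pos <- pos + 4
          ilen <- .le_uint(raw[pos:(pos + 3)]); pos <- pos + 4
          if (itag != "FFFEE000") stop_format("malformed sequence item tag")
          if (ilen == 0xFFFFFFFF) {
            r <- .dcm_parse(raw, pos, sq_end, explicit, stop_tag = "FFFEE00D")
          } else {
            r <- .dcm_parse(raw, pos, pos + ilen - 1, explicit)
          }
          items[[length(items) + 1L]] <- r$elements
          pos <- r$pos
        }
        pos <- sq_end + 1
      }
      out[[tag]] <- items
    } else {
      if (len == 0xFFFFFFFF) stop_format("undefined length on non-sequence element")
      val <- if (len > 0) raw[pos:(pos + len - 1)] else raw(0)
      pos <- pos + len
      out[[tag]] <- .dcm_decode(vr, val)
    }
  }
  list(elements = out, pos = pos)
}

# Read and parse a part-10 DICOM file into a named element list.
dcm_read <- function(path) {
  if (!file.exists(path)) stop_format(sprintf("file not found: %s", path))
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 140 || rawToChar(raw[129:132]) != "DICM")
    stop_format(sprintf("not a DICOM part-10 file: %s", path))
  pos <- 133
  r <- .dcm_parse(raw, pos, pos + 11, explicit = TRUE)  # (0002,0000) only
  glen <- r$elements[["00020000"]]
  if (is.null(glen)) stop_format("missing file meta group length")
  meta <- .dcm_parse(raw, r$pos, r$pos + glen - 1, explicit = TRUE)
  ts <- meta$elements[["00020010"]]
  explicit <- is.null(ts) || ts != "1.2.840.10008.1.2"
  if (!is.null(ts) && !ts %in% c("1.2.840.10008.1.2", "1.2.840.10008.1.2.1"))
    stop_format(sprintf("unsupported transfer syntax: %s", ts))
  body <- .dcm_parse(raw, meta$pos, length(raw), explicit = explicit)
  c(meta$elements, body$elements)
}

# Depth-first search for a tag, descending into sequences.
dcm_find <- function(elements, tag) {
  if (!is.null(elements[[tag]])) return(elements[[tag]])
  for (el in elements) {
    if (is.list(el)) {
      for (item in el) {
        if (is.list(item)) {
          hit <- dcm_find(item, tag)
          if (!is.null(hit)) return(hit)
        }
      }
    }
  }
  NULL
}

#' Read a DICOM RT Dose file
#'
#' Recovers the absorbed-dose grid (stored integers times the dose-grid
#' scaling factor, in Gy) and its physical geometry from the image position,
#' pixel spacing and grid frame offset vector. Only axis-aligned grids
#' (identity image orientation) with uniform frame offsets are supported —
#' the audit phantoms are always scanned axis-aligned.
#'
#' @param path path to a DICOM RT Dose file (explicit or implicit VR little
#'   endian).
#' @return a [dose_grid_3d()] object.
#' @export
read_rt_dose <- function(path) {
  ds <- dcm_read(path)
  modality <- ds[["00080060"]]
  if (!is.null(modality) && !identical(modality, "RTDOSE"))
    stop_format(sprintf("not an RT Dose object (Modality '%s')", modality))
  scaling <- ds[["3004000E"]]
  if (is.null(scaling)) stop_format("missing DoseGridScaling (3004,000E)")
  rows <- ds[["00280010"]]; cols <- ds[["00280011"]]
  frames <- ds[["00280008"]]
  ipp <- ds[["00200032"]]; iop <- ds[["00200037"]]
  psp <- ds[["00280030"]]; gfov <- ds[["3004000C"]]
  bits <- ds[["00280100"]]; pixrep <- ds[["00280103"]]
  pix <- ds[["7FE00010"]]
  for (nm in c("rows", "cols", "frames", "ipp", "iop", "psp", "gfov", "pix")) {
    if (is.null(get(nm))) stop_format(sprintf("missing required RT Dose element (%s)", nm))
  }
  if (max(abs(iop - c(1, 0, 0, 0, 1, 0))) > 1e-6)
    stop_geometry("oblique image orientation is not supported (axis-aligned grids only)")
  if (!is.null(bits) && bits != 16L)
    stop_format(sprintf("unsupported BitsAllocated %d (expected 16)", bits))
  if (length(gfov) != frames)
    stop_format("GridFrameOffsetVector length does not match NumberOfFrames")
  if (frames >= 2) {
    dz <- diff(gfov)
    if (any(dz <= 0) || max(dz) - min(dz) > 1e-6)
      stop_geometry("non-uniform frame offsets are not supported")
    dz <- mean(dz)
  } else {
    dz <- 1
  }
  signed <- !is.null(pixrep) && pixrep == 1L
  stored <- as.numeric(readBin(pix, "integer", n = length(pix) / 2, size = 2,
                               signed = signed, endian = "little"))
  if (length(stored) != rows * cols * frames)
    stop_format("pixel data size does not match Rows x Columns x Frames")
  # DICOM pixel order: column fastest within a row, rows within a frame.
  vals <- array(stored * scaling, dim = c(cols, rows, frames))
  dose_grid_3d(vals,
               origin = c(ipp[1], ipp[2], ipp[3] + gfov[1]),
               spacing = c(psp[2], psp[1], dz))
}

#' Read a DICOM RT Plan file
#'
#' Extracts the isocenter (first control point of the first beam), the
#' planned fraction count and the target prescription dose. Fraction count
#' and prescription are reported as `NA` when the file does not carry them;
#' a plan without any isocenter is rejected.
#'
#' @param path path to a DICOM RT Plan file.
#' @return a [plan_info()] object.
#' @export
read_rt_plan <- function(path) {
  ds <- dcm_read(path)
  modality <- ds[["00080060"]]
  if (!is.null(modality) && !identical(modality, "RTPLAN"))
    stop_format(sprintf("not an RT Plan object (Modality '%s')", modality))
  iso <- dcm_find(ds, "300A012C")
  if (is.null(iso) || length(iso) != 3)
    stop_format("no beam isocenter found in RT Plan")
  nfx <- dcm_find(ds, "300A0078")
  rx <- dcm_find(ds, "300A0026")
  machine <- dcm_find(ds, "300A00B2")
  plan_info(isocenter = iso,
            n_fractions = if (is.null(nfx)) NA else nfx[1],
            prescription_dose = if (is.null(rx)) NA else rx[1],
            machine = if (is.null(machine)) NA_character_ else machine)
}
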