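#' Parse plate-image filenames into their metadata key
#'
#' Filenames follow the acquisition scheme
#' `(WELL)_(IMAGE IN WELL)_(CHANNEL)_(IMAGE NUMBER)`, e.g.
#' `B4_2_GFP_2.tif`: well, tile-scan field index, channel token, and an
#' image number. Well names are normalised to an uppercase letter plus an
#' unpadded integer (`b04` -> `B4`).
#'
#' @param filename character vector of filenames (an optional `.tif` /
#'   `.tiff` extension and any leading path are ignored).
#' @return A tibble with columns `well`, `field`, `channel`,
#'   `image_number` and `filename`, one row per input.
#' @export
#' @examples
#' parse_image_key("B4_2_GFP_2.tif")
parse_image_key <- function(filename) {
  base <- sub("\\.tiff?$", "", basename(filename), ignore.case = TRUE)
  m <- regmatches(base,
                  regexec("^([A-Pa-p])0*([0-9]{1,2})_([0-9]+)_([A-Za-z0-9]+)_([0-9]+)$",
                          base))
  bad <- lengths(m) == 0
  if (any(bad))
    abort(sprintf("cannot parse image filename(s): %s",
                  paste(basename(filename)[bad], collapse = ", ")))
  tibble(
    well = vapply(m, function(g) paste0(toupper(g[2]), g[3]), character(1)),
    field = vapply(m, function(g) as.integer(g[4]), integer(1)),
    channel = vapply(m, function(g) toupper(g[5]), character(1)),
    image_number = vapply(m, function(g) as.integer(g[6]), integer(1)),
    filename = basename(filename))
}

#' Format an image key back into its filename
#'
#' Inverse of [parse_image_key()] on the valid-key domain.
#'
#' @param well,field,channel,image_number key components (vectorised).
#' @param ext file extension, default `"tif"`; `""` for none.
#' @return character vector of filenames.
#' @export
format_image_key <- function(well, field, channel, image_number, ext = "tif") {
  stopifnot(all(grepl("^[A-Pa-p][0-9]{1,2}$", well)))
  well <- paste0(toupper(substr(well, 1, 1)),
                 as.integer(substring(well, 2)))
  base <- sprintf("%s_%d_%s_%d", well, as.integer(field),
                  toupper(channel), as.integer(image_number))
  if (nzchar(ext)) paste0(base, ".", ext) else base
}

#' Read / write a single-plane grayscale field image
#'
#' Fields are stored as single-plane grayscale TIFFs in camera units
#' (integer digital numbers); `read_field` rescales the \[0,1\] TIFF
#' samples back to camera units using the file's bit depth.
#'
#' @param path TIFF file path.
#' @return `read_field`: a numeric matrix of intensities in camera units.
#' @export
read_field <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such image file: %s", path))
  x <- tryCatch(tiff::readTIFF(path, info = TRUE),
                error = function(e)
                  abort(sprintf("unreadable TIFF %s: %s", path,
                                conditionMessage(e))))
  bits <- attr(x, "bits.per.sample") %||% 16L
  if (length(dim(x)) == 3) x <- x[, , 1]
  matrix(round(x * (2^bits - 1)), nrow(x), ncol(x))
}

#' @rdname read_field
#' @param pixels numeric matrix in camera units.
#' @param bit_depth bits per sample for the written file.
#' @export
write_field <- function(path, pixels, bit_depth = 16L) {
  assert_image(pixels)
  tiff::writeTIFF(clamp(pixels, 0, 2^bit_depth - 1) / (2^bit_depth - 1),
                  path, bits.per.sample = as.integer(bit_depth))
  invisible(path)
}

#' Inventory the parseable plate images in a directory
#'
#' @param dir directory containing plate TIFFs.
#' @return Tibble of parsed keys (see [parse_image_key()]) sorted in
#'   row-major well order, one row per image file.
#' @export
plate_inventory <- function(dir) {
  files <- list.files(dir, pattern = "\\.tiff?$", ignore.case = TRUE)
  if (!length(files))
    return(tibble(well = character(), field = integer(),
                  channel = character(), image_number = integer(),
                  filename = character()))
  inv <- parse_image_key(files)
  inv[order(substr(inv$well, 1, 1), as.integer(substring(inv$well, 2)),
            inv$field, inv$channel, inv$image_number), ]
}

#' Load a plate directory as paired two-channel fields
#'
#' Groups a directory of field TIFFs by well and field and pairs the GFP
#' channel with its same-key nuclear-channel partner. Pairing is
#' independent of filesystem listing order. Unpaired keys are reported
#' with a warning (or are the norm in `gfp_only` mode, used for live-cell
#' counting where no nuclear stain is present).
#'
#' @param dir directory of plate TIFFs named per the acquisition scheme.
#' @param channels length-2 character: the nuclear and reporter channel
#'   tokens, default `c("DAPI", "GFP")`.
#' @param gfp_only if `TRUE`, fields need only the reporter channel.
#' @return A tibble with one row per (well, field): columns `well`,
#'   `field`, and list-columns `dapi` and `gfp` holding pixel matrices
#'   (`dapi` entries are `NULL` in `gfp_only` mode). The attribute
#'   `"unpaired"` holds the keys that lacked a partner.
#' @export
load_plate <- function(dir, channels = c("DAPI", "GFP"), gfp_only = FALSE) {
  inv <- plate_inventory(dir)
  inv <- inv[inv$channel %in% toupper(channels), ]
  if (anyDuplicated(inv[c("well", "field", "channel")]))
    abort("duplicate image keys in plate directory")
  nuc <- toupper(channels[1]); rep_ch <- toupper(channels[2])
  wide <- tidyr::pivot_wider(inv[c("well", "field", "channel", "filename")],
                             names_from = "channel",
                             values_from = "filename")
  if (!rep_ch %in% names(wide)) wide[[rep_ch]] <- NA_character_
  if (!nuc %in% names(wide)) wide[[nuc]] <- NA_character_
  need <- if (gfp_only) !is.na(wide[[rep_ch]])
          else !is.na(wide[[rep_ch]]) & !is.na(wide[[nuc]])
  unpaired <- wide[!need, c("well", "field")]
  if (nrow(unpaired) && !gfp_only)
    warn(sprintf("%d field(s) lack a channel partner: %s", nrow(unpaired),
                 paste(utils::head(paste0(unpaired$well, "_", unpaired$field), 5),
                       collapse = ", ")))
  wide <- wide[need, ]
  wide <- wide[order(substr(wide$well, 1, 1),
                     as.integer(substring(wide$well, 2)), wide$field), ]
  out <- tibble(
    well = wide$well, field = wide$field,
    dapi = lapply(wide[[nuc]], function(f)
      if (is.na(f)) NULL else read_field(file.path(dir, f))),
    gfp = lapply(wide[[rep_ch]], function(f) read_field(file.path(dir, f))))
  shapes <- unique(t(vapply(out$gfp, dim, integer(2))))
  if (nrow(shapes) > 1) abort("inconsistent image shapes within plate")
  attr(out, "unpaired") <- unpaired
  out
}
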