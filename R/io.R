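## On-disk formats: multi-page TIFF stacks with JSON sidecars, 16-bit label
## TIFFs, two-column IRF text files, and CSV cell tables. Every writer embeds
## the RNG seed and a config hash so outputs are traceable to their run.

.sidecarPath <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

## FNV-1a over the serialized object; stable within a package version
#' Short content hash of a run configuration
#'
#' @param config any R object, typically a \linkS4class{FlimConfig}.
#' @return 8-hex-digit character hash.
#' @export
configHash <- function(config) {
  bytes <- as.integer(serialize(config, NULL, version = 2L))
  h <- 0
  for (chunk in split(bytes, ceiling(seq_along(bytes) / 4096))) {
    ## vector-friendly FNV variant: polynomial accumulation mod 2^31-1
    h <- (h * 31 + sum(chunk * (33^(seq_along(chunk) %% 7)))) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}

#' Write a FLIM stack to a multi-page TIFF with JSON sidecar
#'
#' Each time bin becomes one 16-bit TIFF page; bin width, channel, pixel
#' size, seed and config hash go to \code{<path>.json} (with the .tif
#' extension replaced).
#'
#' @param stack a \linkS4class{FlimStack} with counts < 65536.
#' @param path output path ending in .tif/.tiff.
#' @param seed,config optional provenance recorded in the sidecar.
#' @return \code{path}, invisibly.
#' @export
writeFlimStack <- function(stack, path, seed = NA_integer_, config = NULL) {
  stopifnot(is(stack, "FlimStack"))
  a <- stack@counts
  if (max(a) > 65535)
    stop("counts exceed 16-bit TIFF range; split or rescale acquisition")
  pages <- lapply(seq_len(dim(a)[1L]), function(tb) a[tb, , ] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  meta <- list(format = "flimetry FLIM stack", n_time_bins = dim(a)[1L],
               bin_width_ns = stack@binWidthNs, channel = stack@channel)
  if (!is.na(stack@pixelSizeUm)) meta$pixel_size_um <- stack@pixelSizeUm
  if (!is.na(seed)) meta$seed <- as.integer(seed)
  if (!is.null(config)) meta$config_hash <- configHash(config)
  jsonlite::write_json(meta, .sidecarPath(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a FLIM stack written by \code{\link{writeFlimStack}}
#'
#' @param path multi-page TIFF path; the JSON sidecar is required.
#' @return a \linkS4class{FlimStack}; round-trips bit-exactly.
#' @export
readFlimStack <- function(path) {
  side <- .sidecarPath(path)
  if (!file.exists(side))
    stop("metadata required: missing sidecar ", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  if (is.null(meta$bin_width_ns) || is.null(meta$channel))
    stop("metadata required: sidecar lacks bin_width_ns or channel")
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- dim(pages[[1L]])
  a <- array(0L, c(length(pages), d[1L], d[2L]))
  for (tb in seq_along(pages)) a[tb, , ] <- pages[[tb]]
  if (any(a < 0)) stop("validation failure: negative counts in ", path)
  flimStack(a, meta$bin_width_ns, meta$channel,
            if (is.null(meta$pixel_size_um)) NA_real_ else meta$pixel_size_um)
}

#' Write an integer label mask as 16-bit TIFF
#'
#' @param mask integer matrix, background 0, labels < 65536.
#' @param path output .tif path.
#' @return \code{path}, invisibly.
#' @export
writeLabelMask <- function(mask, path) {
  if (any(mask < 0) || max(mask) > 65535)
    stop("labels must be in [0, 65535]")
  tiff::writeTIFF(mask / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read an integer label mask
#'
#' @param path a 16-bit TIFF written by \code{\link{writeLabelMask}}.
#' @return integer matrix.
#' @export
readLabelMask <- function(path) {
  m <- tiff::readTIFF(path, as.is = TRUE)
  storage.mode(m) <- "integer"
  m
}

#' Write the three masks of a LabelMasks object
#'
#' Files \code{<prefix>_nuclei.tif}, \code{<prefix>_cells.tif},
#' \code{<prefix>_cytoplasm.tif}.
#'
#' @param masks a \linkS4class{LabelMasks}.
#' @param prefix path prefix.
#' @return character vector of the three paths, invisibly.
#' @export
writeLabelMasks <- function(masks, prefix) {
  stopifnot(is(masks, "LabelMasks"))
  paths <- paste0(prefix, "_", c("nuclei", "cells", "cytoplasm"), ".tif")
  writeLabelMask(masks@nuclei, paths[1L])
  writeLabelMask(masks@cells, paths[2L])
  writeLabelMask(masks@cytoplasm, paths[3L])
  invisible(paths)
}

## canonical cell-table column order; extras are appended alphabetically
.cellTableColumns <- c("patient_id", "condition", "cell_id",
                       "nadh_tau1", "nadh_tau2", "nadh_alpha1", "nadh_tau_m",
                       "nadh_intensity",
                       "fad_tau1", "fad_tau2", "fad_alpha1", "fad_tau_m",
                       "fad_intensity", "redox_ratio",
                       "norm_redox_ratio", "norm_nadh_tau_m",
                       "norm_fad_tau_m", "omi_index")

#' Write a per-cell feature table as CSV
#'
#' One row per cell; snake_case headers in a stable canonical order with
#' \code{patient_id} and \code{condition} always present. A leading
#' '#'-comment line records the seed and config hash.
#'
#' @param records nonempty data.frame of cell records.
#' @param path output .csv path.
#' @param seed,config optional provenance for the comment line.
#' @return \code{path}, invisibly.
#' @export
writeCellTable <- function(records, path, seed = NA_integer_, config = NULL) {
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop("records must be a nonempty data.frame")
  need <- c("patient_id", "condition", "cell_id")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("cell table lacks required columns: ", paste(miss, collapse = ", "))
  key <- do.call(paste, c(records[need], sep = "\r"))
  if (anyDuplicated(key))
    stop("duplicate (patient_id, condition, cell_id) rows")
  known <- intersect(.cellTableColumns, names(records))
  extra <- sort(setdiff(names(records), .cellTableColumns))
  records <- records[, c(known, extra), drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# flimetry cell table; seed=%s; config_hash=%s",
                     seed, if (is.null(config)) NA else configHash(config)),
             con)
  utils::write.csv(records, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a cell table written by \code{\link{writeCellTable}}
#'
#' @param path CSV path ('#' comment lines are skipped).
#' @return data.frame of cell records.
#' @export
readCellTable <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Write an IRF as two-column text
#'
#' Columns \code{time_ns} (bin centers) and \code{weight}.
#'
#' @param irf an \linkS4class{InstrumentResponse}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeIrf <- function(irf, path) {
  stopifnot(is(irf, "InstrumentResponse"))
  tt <- (seq_along(irf@kernel) - 0.5) * irf@binWidthNs
  utils::write.table(data.frame(time_ns = tt, weight = irf@kernel), path,
                     row.names = FALSE, quote = FALSE, sep = "\t")
  invisible(path)
}

#' Read an IRF from two-column text
#'
#' @param path file with columns time_ns, weight (uniform grid).
#' @return an \linkS4class{InstrumentResponse}.
#' @export
readIrf <- function(path) {
  d <- utils::read.table(path, header = TRUE)
  if (!all(c("time_ns", "weight") %in% names(d)))
    stop("metadata required: IRF file needs time_ns and weight columns")
  dt <- diff(d$time_ns)
  if (any(abs(dt - dt[1L]) > 1e-9 * dt[1L]))
    stop("IRF time grid must be uniform")
  instrumentResponse(d$weight, dt[1L])
}

#' Write a LifetimeImageSet as per-variable float TIFFs
#'
#' One 32-bit TIFF per map (\code{tau1}, \code{tau2}, \code{alpha1},
#' \code{tau_m}, \code{intensity}), values divided by a per-variable scale
#' stored in the JSON sidecar (the tiff format stores [0,1] floats), plus a
#' validity-mask TIFF. Precision is single-float (~1e-7 relative).
#'
#' @param lis a \linkS4class{LifetimeImageSet}.
#' @param prefix path prefix for \code{<prefix>_<var>.tif} files.
#' @param seed,config optional provenance for the sidecar.
#' @return sidecar path, invisibly.
#' @export
writeLifetimeImageSet <- function(lis, prefix, seed = NA_integer_,
                                  config = NULL) {
  stopifnot(is(lis, "LifetimeImageSet"))
  maps <- list(tau1 = lis@tau1, tau2 = lis@tau2, alpha1 = lis@alpha1,
               tau_m = lis@tauM, intensity = lis@intensity)
  scales <- list()
  for (v in names(maps)) {
    m <- maps[[v]]
    m[is.na(m)] <- 0
    sc <- max(m, 1e-12)
    scales[[v]] <- sc
    tiff::writeTIFF(m / sc, paste0(prefix, "_", v, ".tif"),
                    bits.per.sample = 32L)
  }
  tiff::writeTIFF(lis@validMask * 1, paste0(prefix, "_valid.tif"),
                  bits.per.sample = 8L)
  side <- paste0(prefix, "_meta.json")
  jsonlite::write_json(
    list(format = "flimetry lifetime maps", channel = lis@channel,
         scales = scales, seed = seed,
         config_hash = if (is.null(config)) NA else configHash(config)),
    side, auto_unbox = TRUE, digits = NA)
  invisible(side)
}

#' Read a LifetimeImageSet written by \code{\link{writeLifetimeImageSet}}
#'
#' @param prefix the path prefix used when writing.
#' @return a \linkS4class{LifetimeImageSet}.
#' @export
readLifetimeImageSet <- function(prefix) {
  side <- paste0(prefix, "_meta.json")
  if (!file.exists(side)) stop("metadata required: missing sidecar ", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  valid <- tiff::readTIFF(paste0(prefix, "_valid.tif")) > 0.5
  rd <- function(v) {
    m <- tiff::readTIFF(paste0(prefix, "_", v, ".tif")) * meta$scales[[v]]
    m
  }
  tau1 <- rd("tau1"); tau2 <- rd("tau2"); alpha1 <- rd("alpha1")
  tauM <- rd("tau_m")
  tau1[!valid] <- NA; tau2[!valid] <- NA; alpha1[!valid] <- NA
  tauM[!valid] <- NA
  new("LifetimeImageSet", tau1 = tau1, tau2 = tau2, alpha1 = alpha1,
      tauM = tauM, intensity = rd("intensity"), validMask = valid,
      channel = meta$channel)
}
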