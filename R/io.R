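#' Read an intensity volume from disk
#'
#' Accepts a multi-page TIFF, or a directory of equally sized PNG/TIFF
#' slices stacked in lexicographic filename order (slice 1 = mound base).
#' RGB slices are routed through [toGrayscale()]; 8-bit grayscale values
#' are kept as integers in \[0, 255\].
#'
#' @param path a TIFF file or slice directory.
#' @param pxUm in-plane pixel spacing, um/pixel (default 3.3).
#' @param sliceUm slice spacing, um.
#' @return an [IntensityVolume-class] object.
#' @export
readVolume <- function(path, pxUm = 3.3, sliceUm = pxUm) {
  readOne <- function(f) {
    ext <- tolower(tools::file_ext(f))
    img <- switch(ext,
      png = round(png::readPNG(f) * 255),
      tif = ,
      tiff = tiff::readTIFF(f, as.is = TRUE),
      stop("unsupported slice format: ", f, call. = FALSE)
    )
    if (length(dim(img)) == 3) {
      if (dim(img)[3] == 4) img <- img[, , 1:3] # drop alpha
      img <- toGrayscale(img)
    }
    img
  }
  if (dir.exists(path)) {
    files <- sort(list.files(path,
      pattern = "\\.(png|tif|tiff)$",
      ignore.case = TRUE, full.names = TRUE
    ))
    if (!length(files)) stop("no PNG/TIFF slices in ", path, call. = FALSE)
    slices <- lapply(files, readOne)
    d1 <- dim(slices[[1]])
    for (i in seq_along(slices)) {
      if (!identical(dim(slices[[i]]), d1)) {
        stop("slice dimensions differ: ", basename(files[i]), call. = FALSE)
      }
    }
  } else {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    slices <- lapply(pages, function(img) {
      if (length(dim(img)) == 3) toGrayscale(img) else img
    })
  }
  vol <- array(0, dim = c(dim(slices[[1]]), length(slices)))
  for (i in seq_along(slices)) vol[, , i] <- slices[[i]]
  intensityVolume(vol, pxUm = pxUm, sliceUm = sliceUm)
}

#' Write an intensity volume as a multi-page TIFF
#'
#' Values are quantized to 8-bit (rounded) on write, so a round trip through
#' [readVolume()] reproduces integer-valued volumes exactly.
#'
#' @param volume an [IntensityVolume-class] object.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
writeVolume <- function(volume, path) {
  stopifnot(is(volume, "IntensityVolume"))
  planes <- lapply(seq_len(dim(volume@data)[3]), function(z) {
    round(volume@data[, , z]) / 255
  })
  tiff::writeTIFF(planes, path, bits.per.sample = 8)
  invisible(path)
}

.runConfigKeys <- c("command", "seed", "outDir", "logLevel", "params")

#' Load and validate a run configuration
#'
#' Reads a YAML configuration (known top-level keys: `command`, `seed`,
#' `outDir`, `logLevel`, `params`), fills defaults, applies flag-style
#' overrides (overrides win over file values) and rejects unknown keys.
#' An empty file yields a valid all-defaults configuration.
#'
#' @param path YAML file, or `NULL` for defaults only.
#' @param overrides named list of overriding values; `params` entries are
#'   merged key-wise.
#' @return a list with the validated configuration plus a `hash` stamp of
#'   the effective configuration.
#' @export
loadRunConfig <- function(path = NULL, overrides = list()) {
  cfg <- list(
    command = NA_character_, seed = 1L, outDir = ".", logLevel = "info",
    params = list()
  )
  fromFile <- list()
  if (!is.null(path)) {
    fromFile <- yaml::read_yaml(path)
    if (is.null(fromFile)) fromFile <- list()
  }
  for (src in list(fromFile, overrides)) {
    unknown <- setdiff(names(src), .runConfigKeys)
    if (length(unknown)) {
      stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
        call. = FALSE
      )
    }
    for (k in names(src)) {
      if (k == "params") {
        for (pk in names(src$params)) cfg$params[[pk]] <- src$params[[pk]]
      } else {
        cfg[[k]] <- src[[k]]
      }
    }
  }
  if (!is.null(cfg$seed)) {
    if (!is.numeric(cfg$seed) || length(cfg$seed) != 1 ||
      cfg$seed != round(cfg$seed)) {
      stop("`seed` must be a single integer", call. = FALSE)
    }
    cfg$seed <- as.integer(cfg$seed)
  }
  if (!is.character(cfg$logLevel) ||
    !cfg$logLevel %in% c("debug", "info", "warn", "error")) {
    stop("`logLevel` must be one of debug/info/warn/error", call. = FALSE)
  }
  cfg$hash <- .configHash(cfg[setdiff(names(cfg), "hash")])
  cfg
}

#' Write a CSV with a reproducibility header
#'
#' Prepends comment lines carrying the package version, the seed and the
#' effective-configuration hash, so two runs with equal configuration hash
#' and seed produce byte-identical files.
#'
#' @param df data.frame to write.
#' @param path output path.
#' @param seed the run seed.
#' @param configHash configuration fingerprint (see [loadRunConfig()]).
#' @return `path`, invisibly.
#' @export
writeRunCsv <- function(df, path, seed = NA_integer_, configHash = "") {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf(
    "# myxofruit %s | seed: %s | config: %s",
    as.character(utils::packageVersion("myxofruit")), seed, configHash
  ), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}
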