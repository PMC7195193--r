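#' Read and validate a pipeline run configuration
#'
#' The YAML config holds a global seed, input/output paths and one
#' parameter block per stage (simulate, distort, puncta, spots, sbr,
#' expansion). Every stage's parameters are validated before any
#' computation starts, so a bad threshold fails fast instead of after a
#' long registration.
#'
#' @param path YAML file path.
#' @return validated config list (class "wormExMConfig").
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  validateRunConfig(cfg)
  structure(cfg, class = "wormExMConfig", file = path)
}

#' @rdname readRunConfig
#' @param cfg a config list.
#' @export
validateRunConfig <- function(cfg) {
  if (is.null(cfg$seed) || !is.numeric(cfg$seed))
    stop("config must set a numeric 'seed'")
  p <- cfg$puncta
  if (!is.null(p$prominence) &&
      (p$prominence <= 0 || p$prominence > 1))
    stop("puncta prominence threshold must be in (0, 1]")
  if (!is.null(p$window) && (p$window < 1 || p$window %% 2 == 0))
    stop("puncta smoothing window must be odd and >= 1")
  sp <- cfg$spots
  for (nm in c("sigma_xy", "sigma_z"))
    if (!is.null(sp[[nm]]) && sp[[nm]] <= 0)
      stop("spots ", nm, " must be positive")
  if (!is.null(sp$threshold) && sp$threshold < 0)
    stop("spots threshold must be >= 0")
  sb <- cfg$sbr
  if (!is.null(sb$p_signal) && (sb$p_signal <= 0 || sb$p_signal >= 100))
    stop("sbr p_signal must be in (0, 100)")
  if (!is.null(sb$p_bg) && (length(sb$p_bg) != 2 || sb$p_bg[1] >= sb$p_bg[2]))
    stop("sbr p_bg must be an increasing pair")
  d <- cfg$distort
  if (!is.null(d$n_pairs) && d$n_pairs < 1000)
    stop("distort n_pairs must be >= 1000")
  invisible(TRUE)
}

#' Run one pipeline stage from a config
#'
#' Executes a stage and writes its outputs plus a JSON manifest (stage,
#' seed, package version, parameters, md5 checksums of inputs and outputs)
#' alongside, so a run can be reproduced and verified. Rerunning with the
#' same config and seed reproduces outputs bit-exactly. On failure,
#' partial outputs are removed.
#'
#' @param cfg config list from \code{\link{readRunConfig}}.
#' @param stage one of "simulate", "distort", "puncta", "spots", "sbr",
#'   "expansion".
#' @param outDir output directory (created if missing).
#' @return invisible list of written file paths.
#' @export
runStage <- function(cfg, stage = c("simulate", "distort", "puncta",
                                    "spots", "sbr", "expansion"),
                     outDir = ".") {
  stage <- match.arg(stage)
  validateRunConfig(cfg)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  floatRanges <- list()
  out <- function(f) file.path(outDir, f)
  note <- function(f) { written <<- c(written, f); f }
  writeFloat <- function(m, f) floatRanges[[basename(f)]] <<- writeFloatTiff(m, f)
  seed <- cfg$seed
  ok <- FALSE
  on.exit(if (!ok) unlink(written), add = TRUE)

  if (stage == "simulate") {
    sc <- cfg$simulate
    spec <- do.call(phantomSpec, c(list(seed = seed),
                                   sc[intersect(names(sc),
                                                names(formals(phantomSpec)))]))
    ph <- generatePhantom(spec)
    writeFloat(imgData(ph$pre), note(out("pre.tif")))
    writeFloat(imgData(ph$post), note(out("post.tif")))
    writeFloat(imgData(ph$truth@foregroundMask) * 1, note(out("masks.tif")))
    tj <- list(
      eTrue = ph$truth@deformation@eTrue,
      sigmaD = ph$truth@deformation@sigmaD,
      ell = ph$truth@deformation@ell,
      punctaPre = ph$truth@punctaPre,
      punctaPost = ph$truth@punctaPost,
      midlineLengthPre = ph$truth@midlineLengthPre,
      midlineLengthPost = ph$truth@midlineLengthPost)
    jsonlite::write_json(tj, note(out("truth.json")), auto_unbox = TRUE,
                         digits = NA)
  } else if (stage == "distort") {
    d <- cfg$distort
    pre <- readImageField(d$pre, d$pixel_size_pre, 1)
    post <- readImageField(d$post, d$pixel_size_post,
                           if (is.null(d$expansion_factor)) 1 else d$expansion_factor)
    rig <- registerRigid(pre, post)
    aligned <- resampleToPre(post, rig, pre)
    res <- registerNonrigid(pre, aligned, rig,
                            gridSpacingUm = d$grid_spacing %||% 10)
    curve <- rmsErrorCurve(res, nPairs = d$n_pairs %||% 10000,
                           bins = seq(0, d$max_bin %||% 100,
                                      by = d$bin_width %||% 1),
                           seed = seed)
    df <- data.frame(bin_center_um = curve$binCenter,
                     rms_error_um = curve$rmsError,
                     fractional_error = curve$fractionalError,
                     n_pairs_in_bin = curve$nPairsInBin,
                     seed = seed, grid_spacing_um = d$grid_spacing %||% 10)
    utils::write.csv(df, note(out("rms_error.csv")), row.names = FALSE)
    writeFloat(res@fieldY, note(out("field_y.tif")))
    writeFloat(res@fieldX, note(out("field_x.tif")))
  } else if (stage == "puncta") {
    p <- cfg$puncta
    profiles <- utils::read.csv(p$profiles)
    reports <- lapply(seq_len(ncol(profiles)), function(j) {
      prof <- lineProfile(profiles[[j]][!is.na(profiles[[j]])],
                          source = names(profiles)[j])
      countPeaks(normalizeSmooth(prof, window = p$window %||% 3),
                 prominenceThreshold = p$prominence %||% 0.01)
    })
    df <- data.frame(
      profile_id = names(profiles),
      n_samples = vapply(profiles, function(x) sum(!is.na(x)), numeric(1)),
      peak_count = vapply(reports, function(r) r@count, integer(1)),
      peak_positions = vapply(reports, function(r)
        paste(r@peaks, collapse = ";"), character(1)),
      window = p$window %||% 3, prominence = p$prominence %||% 0.01)
    utils::write.csv(df, note(out("peak_counts.csv")), row.names = FALSE)
  } else if (stage == "spots") {
    sp <- cfg$spots
    img <- readImageField(sp$stack, unlist(sp$voxel_size),
                          sp$expansion_factor %||% 1)
    thr <- sp$threshold
    if (is.null(thr))
      thr <- suggestThreshold(img, sp$sigma_xy %||% 0.2,
                              sp$sigma_z %||% 0.35)$threshold
    spots <- detectSpots(img, sp$sigma_xy %||% 0.2, sp$sigma_z %||% 0.35, thr)
    utils::write.csv(cbind(spots, threshold = thr),
                     note(out("spots.csv")), row.names = FALSE)
    if (!is.null(sp$rois)) {
      rois <- readRoiCsv(sp$rois)
      utils::write.csv(countInRois(spots, rois, img),
                       note(out("counts.csv")), row.names = FALSE)
    }
  } else if (stage == "sbr") {
    sb <- cfg$sbr
    img <- readImageField(sb$image, sb$pixel_size,
                          sb$expansion_factor %||% 1)
    sig <- cropRegion(img, unlist(sb$signal_center), sb$side_um %||% 50)
    bg <- cropRegion(img, unlist(sb$bg_center), sb$side_um %||% 50)
    masks <- percentileMasks(sig, bg, sb$p_signal %||% 98,
                             unlist(sb$p_bg) %||% c(25, 75))
    r <- sbr(sig, bg, masks)
    utils::write.csv(data.frame(image = sb$image,
                                mean_signal = r$meanSignal,
                                mean_background = r$meanBackground,
                                sbr = r$sbr,
                                p_signal = sb$p_signal %||% 98),
                     note(out("sbr.csv")), row.names = FALSE)
  } else if (stage == "expansion") {
    ex <- cfg$expansion
    preT <- utils::read.csv(ex$pre)
    postT <- utils::read.csv(ex$post)
    getLen <- function(df, feat)
      arcLength(as.matrix(df[df$feature == feat, c("y", "x")]))
    fw <- getLen(postT, "worm") / getLen(preT, "worm")
    fg <- getLen(postT, "gel") / getLen(preT, "gel")
    utils::write.csv(data.frame(ExF_worm = fw, ExF_gel = fg,
                                nExF = normalizedExpansion(fw, fg)),
                     note(out("expansion.csv")), row.names = FALSE)
  }

  manifest <- list(stage = stage, seed = seed,
                   version = as.character(utils::packageVersion("wormExM")),
                   params = cfg[[stage]],
                   floatRanges = floatRanges,
                   outputs = as.list(tools::md5sum(written)))
  mf <- file.path(outDir, paste0(stage, "_manifest.json"))
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  ok <- TRUE
  invisible(c(written, mf))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## float32 TIFF writer for real-valued maps (fields, phantom frames).
## TIFF float samples are clamped to [0, 1] by the writer, so values are
## stored min-max normalized; the range is returned for the manifest.
writeFloatTiff <- function(m, path) {
  rng <- range(m)
  mm <- if (diff(rng) > 0) (m - rng[1]) / diff(rng) else m * 0
  if (length(dim(mm)) == 2) {
    tiff::writeTIFF(mm, path, bits.per.sample = 32, reduce = FALSE)
  } else {
    tiff::writeTIFF(lapply(seq_len(dim(mm)[1]), function(z) mm[z, , ]),
                    path, bits.per.sample = 32)
  }
  invisible(rng)
}
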