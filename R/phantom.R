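#' Construct a PhantomSpec
#'
#' Defaults describe the conditions the pipeline is meant to emulate:
#' an L2-scale worm (~90 um midline) with pharyngeal bulbs and a bright
#' nerve ring, dark ellipsoidal nuclei with 1.6-3 um length scales,
#' synaptic puncta along a ventral cord with a minimum spacing, a global
#' expansion of 3.3x with a smooth residual deformation field, confocal
#' PSF-scale blur and sCMOS-like noise (Poisson gain + Gaussian read noise).
#'
#' @param canvasUm pre-frame canvas (y, x) in um.
#' @param pixelSize pre-frame pixel size (um).
#' @param midline n x 2 (y, x) control points (um); default is a gentle
#'   S-curve spanning the canvas.
#' @param bodyRadius nominal body radius (um).
#' @param bulge pharyngeal bulb amplitude (fraction of bodyRadius).
#' @param nerveRingS nerve ring position as a fraction of midline length.
#' @param nerveRingBrightness nerve ring peak intensity / body intensity;
#'   this is the configured signal-to-background contrast of the phantom.
#' @param bodyIntensity,backgroundIntensity intensity levels.
#' @param nNuclei,nucleusAxes,nucleusDepth nuclei count, semi-axis range
#'   (um) and fractional darkening.
#' @param nPuncta,punctaMinSpacing,punctaAmplitude puncta count, minimum
#'   pairwise spacing (um), amplitude range (relative to body intensity).
#' @param psfSigma PSF sigma (um, absolute; identical pre and post because
#'   the optics do not expand with the specimen).
#' @param eTrue,thetaPost,translationPost global similarity of the post
#'   frame; \code{translationPost = c(NA, NA)} auto-centres the worm on an
#'   auto-sized post canvas.
#' @param sigmaD,ell residual deformation amplitude (per-component sd, um)
#'   and correlation length (um).
#' @param textureAmplitude,textureEll multiplicative intensity texture of
#'   the body tissue (relative sd and correlation length, um), emulating
#'   anatomical texture; the texture deforms with the specimen.
#' @param noiseGain,noiseSigmaRead noise model Poisson(I * gain)/gain +
#'   N(0, sigmaRead); 0 disables each term.
#' @param seed integer seed; geometry and noise use two sub-streams
#'   (seed and seed + 1) so noise can be varied at fixed geometry.
#' @return A \linkS4class{PhantomSpec}.
#' @export
phantomSpec <- function(canvasUm = c(100, 100), pixelSize = 0.32,
                        midline = NULL, bodyRadius = 6, bulge = 0.6,
                        nerveRingS = 0.10, nerveRingBrightness = 3,
                        bodyIntensity = 1, backgroundIntensity = 0.1,
                        nNuclei = 60, nucleusAxes = c(0.8, 1.5),
                        nucleusDepth = 0.7,
                        nPuncta = 30, punctaMinSpacing = 1.0,
                        punctaAmplitude = c(0.8, 1.6), psfSigma = 0.32,
                        eTrue = 3.3, thetaPost = 0.25,
                        translationPost = c(NA_real_, NA_real_),
                        sigmaD = 1.0, ell = 20,
                        textureAmplitude = 0.25, textureEll = 5,
                        noiseGain = 200, noiseSigmaRead = 0.02, seed = 1) {
  if (is.null(midline)) {
    ## asymmetric resting posture so the phantom has no spurious
    ## rotational self-similarity
    x <- c(10, 24, 40, 57, 72, 88) / 100 * canvasUm[2]
    y <- (52 + c(-16, -8, 6, 15, 10, -8)) / 100 * canvasUm[1]
    midline <- cbind(y, x)
  }
  new("PhantomSpec", canvasUm = canvasUm, pixelSize = pixelSize,
      midline = midline, bodyRadius = bodyRadius, bulge = bulge,
      nerveRingS = nerveRingS, nerveRingBrightness = nerveRingBrightness,
      bodyIntensity = bodyIntensity, backgroundIntensity = backgroundIntensity,
      nNuclei = nNuclei, nucleusAxes = nucleusAxes, nucleusDepth = nucleusDepth,
      nPuncta = nPuncta, punctaMinSpacing = punctaMinSpacing,
      punctaAmplitude = punctaAmplitude, psfSigma = psfSigma,
      eTrue = eTrue, thetaPost = thetaPost, translationPost = translationPost,
      sigmaD = sigmaD, ell = ell,
      textureAmplitude = textureAmplitude, textureEll = textureEll,
      noiseGain = noiseGain, noiseSigmaRead = noiseSigmaRead, seed = seed)
}

## Radius profile along the midline: tapered tube with two pharyngeal
## bulbs near the head. s in um, L total length.
radiusProfile <- function(s, L, r0, bulge) {
  taper <- smoothstep(s / 5 - 1) * smoothstep((L - s) / 5 - 1)
  bulbs <- bulge * (0.8 * exp(-((s - 0.06 * L) / 2.5)^2) +
                    exp(-((s - 0.13 * L) / 2.5)^2))
  pmax(r0 * (0.25 + 0.75 * taper) * (1 + bulbs), 0.8)
}

## Evaluate the analytic worm scene at arbitrary pre-frame points
## (n x 2, (y, x) um). `edge` is the softness of object boundaries in
## pre-frame um (the PSF expressed in the frame being rendered: psf for
## the pre image, psf / eTrue for a post image evaluated through the
## inverse map, because the optics do not expand with the specimen).
## Returns the intensity and the component weights used for truth masks.
sceneEval <- function(pts, mid, radii, ring, nuclei, puncta, texFun,
                      bodyI, bgI, ringGain, nucDepth, edge, punctaSigma) {
  n <- nrow(pts)
  bodyW <- numeric(n)
  rNear <- numeric(n)
  dMin <- rep(Inf, n)
  chunk <- 50000L
  for (i0 in seq(1L, n, by = chunk)) {
    ii <- i0:min(i0 + chunk - 1L, n)
    d2 <- outer(rowSums(pts[ii, , drop = FALSE]^2), rowSums(mid^2), "+") -
      2 * (pts[ii, , drop = FALSE] %*% t(mid))
    j <- max.col(-d2, ties.method = "first")
    dMin[ii] <- sqrt(pmax(d2[cbind(seq_along(ii), j)], 0))
    rNear[ii] <- radii[j]
  }
  bodyW <- smoothstep((rNear - dMin) / edge)

  ringW <- numeric(n)
  if (!is.null(ring)) {
    dy <- pts[, 1] - ring$center[1]
    dx <- pts[, 2] - ring$center[2]
    u <- dy * ring$normal[1] + dx * ring$normal[2]
    t_ <- -dy * ring$normal[2] + dx * ring$normal[1]
    ringW <- smoothstep((ring$halfWidth - abs(t_)) / edge) *
      smoothstep((ring$halfLen - abs(u)) / max(edge, 0.5))
  }

  nucW <- numeric(n)
  if (!is.null(nuclei) && nrow(nuclei) > 0) {
    nucEdge <- max(edge, 0.25)
    for (i in seq_len(nrow(nuclei))) {
      a <- nuclei$a[i]; b <- nuclei$b[i]; phi <- nuclei$phi[i]
      rad <- max(a, b) + 3 * nucEdge
      near <- which(abs(pts[, 1] - nuclei$y[i]) < rad &
                    abs(pts[, 2] - nuclei$x[i]) < rad)
      if (!length(near)) next
      dy <- pts[near, 1] - nuclei$y[i]
      dx <- pts[near, 2] - nuclei$x[i]
      q <- sqrt(((cos(phi) * dy + sin(phi) * dx) / a)^2 +
                ((-sin(phi) * dy + cos(phi) * dx) / b)^2)
      v <- smoothstep((1 - q) * min(a, b) / nucEdge)
      nucW[near] <- pmax(nucW[near], v)
    }
  }

  punctW <- numeric(n)
  if (!is.null(puncta) && nrow(puncta) > 0) {
    for (i in seq_len(nrow(puncta))) {
      rad <- 4 * punctaSigma
      near <- which(abs(pts[, 1] - puncta$y[i]) < rad &
                    abs(pts[, 2] - puncta$x[i]) < rad)
      if (!length(near)) next
      d2 <- (pts[near, 1] - puncta$y[i])^2 + (pts[near, 2] - puncta$x[i])^2
      punctW[near] <- punctW[near] +
        puncta$amp[i] * exp(-d2 / (2 * punctaSigma^2))
    }
  }

  tex <- if (is.null(texFun)) 1 else pmax(1 + texFun(pts), 0.2)
  img <- bgI + bodyI * bodyW * (1 - nucDepth * nucW) *
    (tex * (1 - ringW) + ringGain * ringW) + bodyI * punctW
  list(img = img, body = bodyW, ringW = ringW, nucW = nucW, punct = punctW)
}

## Scalar Gaussian random field on a coarse grid, bilinear evaluation;
## used for the multiplicative tissue texture.
makeScalarGRF <- function(extentUm, amp, ellTex, seed) {
  h <- ellTex / 2
  margin <- 2 * ellTex
  ny <- ceiling((extentUm[1] + 2 * margin) / h) + 1
  nx <- ceiling((extentUm[2] + 2 * margin) / h) + 1
  rng <- localRNG(seed)
  g <- matrix(rng$rnorm(ny * nx), ny, nx)
  g <- smoothArray(g, c(1, 1))
  g <- (g - mean(g)) / stats::sd(g) * amp
  list(grid = g, origin = c(-margin, -margin), h = h)
}

evalScalarGRF <- function(f, points) {
  bilinearSample(f$grid, (points[, 1] - f$origin[1]) / f$h,
                 (points[, 2] - f$origin[2]) / f$h)
}

applyNoise <- function(img, gain, sigmaRead, rng) {
  d <- dim(img)
  if (gain > 0) img <- rng$rpois(length(img), lambda = pmax(img, 0) * gain) / gain
  if (sigmaRead > 0) img <- img + rng$rnorm(length(img), sd = sigmaRead)
  array(pmax(img, 0), d)
}

#' Generate a pre/post-expansion worm phantom pair with ground truth
#'
#' Renders the parametric worm twice: once in the pre-expansion frame and
#' once after the global similarity (scale eTrue, rotation, translation)
#' composed with the smooth residual deformation field. All truth
#' coordinates (puncta, midline) are mapped through the exact forward
#' transform, so post truth equals the deformation applied to pre truth.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @return list with elements \code{pre}, \code{post}
#'   (\linkS4class{ImageField}s) and \code{truth}
#'   (\linkS4class{PhantomTruth}).
#' @export
generatePhantom <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  rngGeom <- localRNG(spec@seed)
  rngNoise <- localRNG(spec@seed + 1)
  px <- spec@pixelSize
  dimsPre <- ceiling(spec@canvasUm / px)

  mid <- resampleCurve(spec@midline, step = 0.5)
  s <- chordLengths(mid)
  L <- s[length(s)]
  radii <- radiusProfile(s, L, spec@bodyRadius, spec@bulge)

  ## project the field's similarity component out over the body support,
  ## i.e. the region registration actually sees
  nrmAll <- cbind(-c(diff(mid[, 2]), 0), c(diff(mid[, 1]), 0))
  nrmAll <- nrmAll / pmax(sqrt(rowSums(nrmAll^2)), 1e-9)
  bodyPts <- rbind(mid, mid + nrmAll * 0.6 * radii, mid - nrmAll * 0.6 * radii)
  def <- makeDeformation(spec@canvasUm, spec@sigmaD, spec@ell,
                         eTrue = spec@eTrue, theta = spec@thetaPost,
                         translation = c(0, 0), seed = spec@seed,
                         projectPoints = bodyPts)

  ## nerve ring geometry at arc fraction nerveRingS
  iRing <- which.min(abs(s - spec@nerveRingS * L))
  tangent <- mid[min(iRing + 1, nrow(mid)), ] - mid[max(iRing - 1, 1), ]
  tangent <- tangent / sqrt(sum(tangent^2))
  normal <- c(-tangent[2], tangent[1])
  ring <- list(center = mid[iRing, ], normal = normal,
               halfLen = radii[iRing] * 0.95, halfWidth = 1.5)

  ## nuclei along the body (geometry stream)
  nNuc <- spec@nNuclei
  nuclei <- NULL
  if (nNuc > 0) {
    sk <- rngGeom$runif(nNuc, 5, L - 5)
    ik <- vapply(sk, function(z) which.min(abs(s - z)), integer(1))
    off <- rngGeom$runif(nNuc, -0.55, 0.55) * radii[ik]
    nrm <- cbind(-diff(mid[, 2])[pmin(ik, nrow(mid) - 1)],
                 diff(mid[, 1])[pmin(ik, nrow(mid) - 1)])
    nrm <- nrm / sqrt(rowSums(nrm^2))
    ctr <- mid[ik, , drop = FALSE] + nrm * off
    nuclei <- data.frame(y = ctr[, 1], x = ctr[, 2],
                         a = rngGeom$runif(nNuc, spec@nucleusAxes[1], spec@nucleusAxes[2]),
                         b = rngGeom$runif(nNuc, spec@nucleusAxes[1], spec@nucleusAxes[2]),
                         phi = rngGeom$runif(nNuc, 0, pi))
  }

  ## puncta along the ventral cord (offset curve), sequential rejection
  ## sampling enforcing the minimum spacing
  cordOff <- 0.45
  cordPoint <- function(z) {
    i <- which.min(abs(s - z))
    j <- pmin(i, nrow(mid) - 1)
    nv <- c(-(mid[j + 1, 2] - mid[j, 2]), mid[j + 1, 1] - mid[j, 1])
    nv <- nv / sqrt(sum(nv^2))
    mid[i, ] + nv * cordOff * radii[i]
  }
  punc <- matrix(numeric(0), 0, 2)
  tries <- 0L
  while (nrow(punc) < spec@nPuncta && tries < spec@nPuncta * 60) {
    cand <- cordPoint(rngGeom$runif(1, 4, L - 4))
    if (nrow(punc) == 0 ||
        min(sqrt(rowSums(sweep(punc, 2, cand)^2))) >= spec@punctaMinSpacing)
      punc <- rbind(punc, cand)
    tries <- tries + 1L
  }
  punctaAmp <- rngGeom$runif(nrow(punc), spec@punctaAmplitude[1],
                             spec@punctaAmplitude[2])

  ## ---- tissue texture (deforms with the specimen) ----
  texFun <- NULL
  if (spec@textureAmplitude > 0) {
    texF <- makeScalarGRF(spec@canvasUm, spec@textureAmplitude,
                          spec@textureEll, spec@seed + 2)
    texFun <- function(p) evalScalarGRF(texF, p)
  }
  punctaDf <- if (nrow(punc))
    data.frame(y = punc[, 1], x = punc[, 2], amp = punctaAmp) else NULL

  ## ---- pre frame render (analytic scene at pixel centres) ----
  edgePre <- max(spec@psfSigma, px)
  gPre <- cbind(rep((seq_len(dimsPre[1]) - 1) * px, dimsPre[2]),
                rep((seq_len(dimsPre[2]) - 1) * px, each = dimsPre[1]))
  scenePre <- sceneEval(gPre, mid, radii, ring, nuclei, punctaDf, texFun,
                        spec@bodyIntensity, spec@backgroundIntensity,
                        spec@nerveRingBrightness, spec@nucleusDepth,
                        edge = edgePre, punctaSigma = spec@psfSigma)
  toM <- function(v) matrix(v, dimsPre[1], dimsPre[2])

  ## ---- post frame canvas ----
  midPost0 <- applyDeformation(def, mid)
  margin <- max(radii) * spec@eTrue + 4 * spec@psfSigma + 3
  if (any(is.na(spec@translationPost))) {
    tPost <- margin - apply(midPost0, 2, min)
    dimsPost <- ceiling((apply(midPost0, 2, max) - apply(midPost0, 2, min) +
                           2 * margin) / px)
  } else {
    tPost <- spec@translationPost
    dimsPost <- ceiling(spec@canvasUm * spec@eTrue / px)
    pad <- radii * spec@eTrue + 4 * spec@psfSigma
    lo <- c(min(midPost0[, 1] - pad), min(midPost0[, 2] - pad)) + tPost
    hi <- c(max(midPost0[, 1] + pad), max(midPost0[, 2] + pad)) + tPost
    if (any(lo < 0) || any(hi > dimsPost * px))
      stop("deformed phantom exceeds the post canvas; needs at least ",
           paste(ceiling(hi - pmin(lo, 0)), collapse = " x "), " um")
  }
  def@translation <- as.numeric(tPost)

  ## ---- post frame render: pre scene evaluated through the exact
  ## inverse map, so every intensity feature (edges included) transforms
  ## by the ground-truth deformation; the PSF stays absolute, giving the
  ## post image its physically finer biological-scale detail ----
  gPost <- cbind(rep((seq_len(dimsPost[1]) - 1) * px, dimsPost[2]),
                 rep((seq_len(dimsPost[2]) - 1) * px, each = dimsPost[1]))
  pPre <- invertDeformation(def, gPost)
  edgePost <- max(spec@psfSigma, px) / spec@eTrue
  scenePost <- sceneEval(pPre, mid, radii, ring, nuclei, punctaDf, texFun,
                         spec@bodyIntensity, spec@backgroundIntensity,
                         spec@nerveRingBrightness, spec@nucleusDepth,
                         edge = edgePost, punctaSigma = spec@psfSigma / spec@eTrue)
  scenePreImg <- toM(scenePre$img)
  scenePostImg <- matrix(scenePost$img, dimsPost[1], dimsPost[2])
  midPost <- midPost0 + matrix(tPost, nrow(midPost0), 2, byrow = TRUE)
  puncPost <- if (nrow(punc)) applyDeformation(def, punc) else punc

  preImg <- applyNoise(scenePreImg, spec@noiseGain, spec@noiseSigmaRead, rngNoise)
  postImg <- applyNoise(scenePostImg, spec@noiseGain, spec@noiseSigmaRead, rngNoise)

  fg <- toM(scenePre$body > 0.5)
  nucM <- toM(scenePre$nucW > 0.5)
  ## strict plateau-core masks so mask means equal the configured levels
  core <- scenePre$body > 0.999
  sigM <- toM(scenePre$ringW > 0.999 & core & scenePre$nucW < 0.01 &
    scenePre$punct < 0.005)
  bgM <- toM(core & scenePre$ringW < 0.01 & scenePre$nucW < 0.01 &
    scenePre$punct < 0.005)

  gelPre <- 2 * sum(spec@canvasUm - 4)        # rectangle inset by 2 um
  truth <- new("PhantomTruth",
    deformation = def,
    punctaPre = punc,
    punctaPost = puncPost,
    foregroundMask = mask(fg, "foreground"),
    nucleiMask = mask(nucM, "background"),
    signalMask = mask(sigM, "signal"),
    backgroundMask = mask(bgM, "background"),
    midlineLengthPre = L,
    midlineLengthPost = sum(sqrt(rowSums(diff(midPost)^2))),
    gelContourPre = gelPre,
    gelContourPost = gelPre * spec@eTrue,
    spots = data.frame(), cellCounts = data.frame())

  list(pre = imageField(preImg, px, 1, "phantom"),
       post = imageField(postImg, px, spec@eTrue, "phantom"),
       truth = truth)
}

#' Generate a 3D multi-cell FISH phantom stack with per-cell truth counts
#'
#' Cells are placed on a jittered 3D grid; each cell has a spherical
#' nucleus and a Poisson-distributed number of transcript spots placed
#' uniformly in the perinuclear shell, with a configurable minority placed
#' inside the nucleus (mimicking nascent transcription sites). Spots are
#' rendered as anisotropic 3D Gaussians on a (z, y, x) voxel grid.
#'
#' @param nCells number of cells.
#' @param lambda per-cell Poisson mean transcript count; scalar or one
#'   value per cell.
#' @param voxelSize (z, y, x) voxel size, um (absolute).
#' @param eTrue expansion factor annotation of the stack.
#' @param nucleusRadiusUm nucleus radius in biological um.
#' @param shellThicknessUm perinuclear shell thickness in biological um.
#' @param nuclearFraction fraction of spots placed inside the nucleus.
#' @param minSpacingUm optional minimum pairwise spot spacing within a
#'   cell (um, absolute); 0 disables the constraint. Useful fixtures for
#'   validating the counting chain without resolution-limited merging.
#' @param sigmaXy,sigmaZ rendered spot sigma, um (absolute).
#' @param amplitude spot amplitude range (length 2) or scalar.
#' @param background constant background level.
#' @param snr spot amplitude / Gaussian noise sd; Inf disables noise.
#' @param seed integer seed.
#' @return list: \code{img} (\linkS4class{ImageField}), \code{rois}
#'   (list of \linkS4class{RoiBox3D}), \code{spots} (truth data.frame with
#'   0-based voxel coordinates), \code{cellCounts} (label, count),
#'   \code{nucleiMask}, \code{somaMask} (\linkS4class{Mask}s).
#' @export
generateFishPhantom <- function(nCells = 50, lambda = 5,
                                voxelSize = c(0.3, 0.15, 0.15), eTrue = 3.3,
                                nucleusRadiusUm = 1.0, shellThicknessUm = 0.5,
                                nuclearFraction = 0.1, minSpacingUm = 0,
                                sigmaXy = 0.2, sigmaZ = 0.35,
                                amplitude = c(0.9, 1.1), background = 0.05,
                                snr = Inf, seed = 1) {
  rngGeom <- localRNG(seed)
  rngNoise <- localRNG(seed + 1)
  if (length(amplitude) == 1) amplitude <- rep(amplitude, 2)
  lambda <- rep_len(lambda, nCells)
  rnAbs <- nucleusRadiusUm * eTrue
  shellAbs <- shellThicknessUm * eTrue
  rCell <- rnAbs + shellAbs
  halfBox <- rCell + 3 * c(sigmaZ, sigmaXy, sigmaXy)  # um, per axis (z,y,x)
  pitch <- 2 * halfBox + 1                             # cell pitch, um

  ## grid layout closest to a cube
  nz <- max(1L, floor(nCells^(1 / 3)))
  ny <- max(1L, ceiling(sqrt(nCells / nz)))
  nx <- ceiling(nCells / (nz * ny))
  dimsUm <- c(nz, ny, nx) * pitch
  dims <- ceiling(dimsUm / voxelSize)

  img <- array(background, dims)
  nucMask <- array(FALSE, dims)
  somaMask <- array(FALSE, dims)
  rois <- vector("list", nCells)
  spots <- NULL
  counts <- integer(nCells)

  cellIdx <- 0L
  for (iz in seq_len(nz)) for (iy in seq_len(ny)) for (ix in seq_len(nx)) {
    if (cellIdx >= nCells) break
    cellIdx <- cellIdx + 1L
    centerUm <- (c(iz, iy, ix) - 0.5) * pitch +
      rngGeom$runif(3, -0.15, 0.15) * c(sigmaZ, sigmaXy, sigmaXy)
    label <- sprintf("cell%03d", cellIdx)
    n <- rngGeom$rpois(1, lambda[cellIdx])
    counts[cellIdx] <- n
    if (n > 0) {
      nuclear <- rngGeom$runif(n) < nuclearFraction
      onePos <- function(isNuc) {
        rr <- if (isNuc) rnAbs * rngGeom$runif(1)^(1 / 3)
              else (rnAbs^3 + (rCell^3 - rnAbs^3) * rngGeom$runif(1))^(1 / 3)
        v <- rngGeom$rnorm(3)
        centerUm + rr * v / sqrt(sum(v^2))
      }
      pos <- matrix(0, n, 3)
      for (si in seq_len(n)) {
        for (try_ in 1:100) {
          cnd <- onePos(nuclear[si])
          if (minSpacingUm <= 0 || si == 1 ||
              min(sqrt(rowSums(sweep(pos[seq_len(si - 1), , drop = FALSE],
                                     2, cnd)^2))) >= minSpacingUm) break
        }
        pos[si, ] <- cnd
      }
      amp <- rngGeom$runif(n, amplitude[1], amplitude[2])
      vox <- sweep(pos, 2, voxelSize, "/")  # 0-based voxel coords
      spots <- rbind(spots, data.frame(z = vox[, 1], y = vox[, 2], x = vox[, 3],
                                       amp = amp, cell = label,
                                       nuclear = nuclear))
      img <- addGauss3d(img, vox, amp, c(sigmaZ, sigmaXy, sigmaXy) / voxelSize)
    }
    ## masks + ROI
    ctrVox <- centerUm / voxelSize
    lo <- pmax(floor(ctrVox - rCell / voxelSize) - 1, 0)
    hi <- pmin(ceiling(ctrVox + rCell / voxelSize) + 1, dims - 1)
    zz <- (lo[1]:hi[1]); yy <- (lo[2]:hi[2]); xx <- (lo[3]:hi[3])
    dz2 <- ((zz - ctrVox[1]) * voxelSize[1])^2
    dy2 <- ((yy - ctrVox[2]) * voxelSize[2])^2
    dx2 <- ((xx - ctrVox[3]) * voxelSize[3])^2
    d2 <- outer(outer(dz2, dy2, "+"), dx2, "+")
    nucMask[zz + 1, yy + 1, xx + 1] <- nucMask[zz + 1, yy + 1, xx + 1] |
      (d2 <= rnAbs^2)
    somaMask[zz + 1, yy + 1, xx + 1] <- somaMask[zz + 1, yy + 1, xx + 1] |
      (d2 <= rCell^2)
    roiLo <- pmax(floor(ctrVox - halfBox / voxelSize), 0)
    roiHi <- pmin(ceiling(ctrVox + halfBox / voxelSize), dims - 1)
    rois[[cellIdx]] <- roiBox3D(roiLo, roiHi, label)
  }

  if (is.finite(snr)) {
    sd_ <- mean(amplitude) / snr
    img <- img + array(rngNoise$rnorm(length(img), sd = sd_), dim(img))
    img[img < 0] <- 0
  }

  list(img = imageField(img, voxelSize, eTrue, "FISH"),
       rois = rois,
       spots = if (is.null(spots)) data.frame() else spots,
       cellCounts = data.frame(label = sprintf("cell%03d", seq_len(nCells)),
                               count = counts, stringsAsFactors = FALSE),
       nucleiMask = mask(nucMask, "signal"),
       somaMask = mask(somaMask, "foreground"))
}

## Add 3D Gaussian blobs at (0-based) voxel coordinates `vox` (n x 3,
## (z,y,x)) with per-axis sigma in voxels.
addGauss3d <- function(img, vox, amp, sigmaVox) {
  dims <- dim(img)
  half <- ceiling(4 * sigmaVox)
  for (i in seq_len(nrow(vox))) {
    c0 <- vox[i, ]
    lo <- pmax(floor(c0 - half), 0)
    hi <- pmin(ceiling(c0 + half), dims - 1)
    if (any(lo > hi)) next
    gz <- exp(-((lo[1]:hi[1]) - c0[1])^2 / (2 * sigmaVox[1]^2))
    gy <- exp(-((lo[2]:hi[2]) - c0[2])^2 / (2 * sigmaVox[2]^2))
    gx <- exp(-((lo[3]:hi[3]) - c0[3])^2 / (2 * sigmaVox[3]^2))
    blob <- amp[i] * outer(outer(gz, gy), gx)
    img[lo[1]:hi[1] + 1, lo[2]:hi[2] + 1, lo[3]:hi[3] + 1] <-
      img[lo[1]:hi[1] + 1, lo[2]:hi[2] + 1, lo[3]:hi[3] + 1] + blob
  }
  img
}

#' Simulate a cohort of worm/gel expansion measurements
#'
#' Gel expansion factors are drawn from a normal distribution (the
#' measured hydrogel variability: mean 3.53, sd 0.16); each specimen's worm
#' expands by a fixed ratio of its gel factor, and traced points carry
#' Gaussian tracing noise. Used to demonstrate that normalizing the worm
#' factor by the gel factor removes the gel variance.
#'
#' @param n cohort size.
#' @param gelMean,gelSd hydrogel expansion factor distribution.
#' @param ratio worm/gel expansion ratio (the true nExF).
#' @param wormLengthUm pre-expansion worm midline length.
#' @param traceNoiseUm sd of tracing noise added to every traced point.
#' @param nTracePoints points per trace.
#' @param seed integer seed.
#' @return data.frame with ExFworm, ExFgel, nExF per specimen.
#' @export
simulateExpansionCohort <- function(n = 52, gelMean = 3.53, gelSd = 0.16,
                                    ratio = 0.97, wormLengthUm = 850,
                                    traceNoiseUm = 1.0, nTracePoints = 15,
                                    seed = 1) {
  rng <- localRNG(seed)
  out <- data.frame(ExFworm = numeric(n), ExFgel = numeric(n), nExF = numeric(n))
  gelSide <- 2000  # mold contour scale, um
  for (i in seq_len(n)) {
    gel <- rng$rnorm(1, gelMean, gelSd)
    worm <- ratio * gel
    t <- seq(0, 1, length.out = nTracePoints)
    base <- cbind(100 + 30 * sin(2 * pi * t), 100 + wormLengthUm * t)
    jit <- function(p, sd_) p + matrix(rng$rnorm(length(p), sd = sd_), nrow(p), 2)
    wormPre <- jit(base, traceNoiseUm)
    wormPost <- jit(base * worm, traceNoiseUm)
    gelT <- seq(0, 1, length.out = 8)
    gelBase <- cbind(rep(50, 8), gelSide * gelT)
    gelPre <- jit(gelBase, traceNoiseUm)
    gelPost <- jit(gelBase * gel, traceNoiseUm)
    fw <- arcLength(wormPost) / arcLength(wormPre)
    fg <- arcLength(gelPost) / arcLength(gelPre)
    out$ExFworm[i] <- fw
    out$ExFgel[i] <- fg
    out$nExF[i] <- normalizedExpansion(fw, fg)
  }
  out
}
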