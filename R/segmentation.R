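#' Maximum Renyi-entropy automatic threshold
#'
#' Selects a grey-level threshold from an image histogram by maximising the
#' sum of background and foreground Renyi entropies, following the
#' published three-order combination rule used by the standard
#' "RenyiEntropy" auto-threshold: candidate thresholds are computed for
#' entropy orders 1/2, 1 (the Shannon/maximum-entropy limit) and 2, sorted,
#' and blended with weights that depend on how far apart they fall (within
#' five grey levels counting as agreement). Ties in any single-order argmax
#' are broken toward the lowest grey level. The result is deterministic and
#' depends on the histogram only.
#'
#' The returned threshold `t` splits grey levels into a background class
#' `<= t` and a foreground class `> t`.
#'
#' @param histogram Integer vector of grey-level counts; element `i` is the
#'   count of grey level `i - 1` (so a 256-bin histogram covers 0-255).
#' @return The threshold grey level (integer-valued numeric).
#' @examples
#' h <- integer(256); h[11] <- 400; h[201] <- 100
#' renyiThreshold(h)   # strictly between grey levels 10 and 200
#' @export
renyiThreshold <- function(histogram) {
  h <- as.numeric(histogram)
  if (any(h < 0) || any(!is.finite(h))) stop("histogram counts must be >= 0")
  if (sum(h > 0) < 2L)
    stop("degenerate histogram: fewer than two occupied grey levels")
  p <- h / sum(h)
  L <- length(p)
  P1 <- cumsum(p)
  P2 <- 1 - P1
  cand <- which(P1 > 0 & P2 > .Machine$double.eps)

  # order 1 (Shannon limit): H_B + H_F with H_B = log P1 - sum(p log p)/P1
  plogp <- ifelse(p > 0, p * log(p), 0)
  A <- cumsum(plogp)
  H1 <- log(P1) - A / P1 + log(P2) - (A[L] - A) / P2

  # order 1/2: 2 [ log S_B - log(P1)/2 ] + foreground analogue,
  # with S = cumsum(sqrt(p))
  S <- cumsum(sqrt(p))
  H05 <- 2 * (log(S) - 0.5 * log(P1)) + 2 * (log(S[L] - S) - 0.5 * log(P2))

  # order 2: -log sum((p/P)^2) per class
  Q <- cumsum(p^2)
  H2 <- 2 * log(P1) - log(Q) + 2 * log(P2) - log(Q[L] - Q)

  pick <- function(H) cand[which.max(H[cand])]   # first max = lowest level
  ts <- sort(c(pick(H05), pick(H1), pick(H2)))
  t1 <- ts[1L]; t2 <- ts[2L]; t3 <- ts[3L]

  beta <- if (abs(t1 - t2) <= 5 && abs(t2 - t3) <= 5) c(1, 2, 1)
    else if (abs(t1 - t2) <= 5 && abs(t2 - t3) > 5)   c(0, 1, 3)
    else if (abs(t1 - t2) > 5 && abs(t2 - t3) <= 5)   c(3, 1, 0)
    else                                              c(1, 2, 1)
  omega <- P1[t3] - P1[t1]
  tstar <- (t1 - 1) * (P1[t1] + 0.25 * omega * beta[1L]) +
    0.25 * (t2 - 1) * omega * beta[2L] +
    (t3 - 1) * (P2[t3] + 0.25 * omega * beta[3L])
  floor(tstar)
}

#' Label connected components in a binary mask
#'
#' Run-based union-find labelling of the foreground (`TRUE`) pixels of a
#' logical matrix, under 8-connectivity (default: edge and corner
#' neighbours) or 4-connectivity (edge neighbours only).
#'
#' @param mask Logical matrix.
#' @param connectivity 8 or 4.
#' @return A list with `labels` (integer matrix, 0 = background, components
#'   numbered from 1), `nComponents`, and `stats`, a `data.frame` with one
#'   row per component: `label`, `pixel_count`, `centroid_x` (column),
#'   `centroid_y` (row).
#' @export
labelComponents <- function(mask, connectivity = 8) {
  stopifnot(is.matrix(mask), is.logical(mask))
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8")
  nr <- nrow(mask)
  nc <- ncol(mask)
  runs_start <- vector("list", nc)
  runs_end <- vector("list", nc)
  nrun <- 0L
  for (j in seq_len(nc)) {
    r <- rle(mask[, j])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    runs_start[[j]] <- starts[keep]
    runs_end[[j]] <- ends[keep]
    nrun <- nrun + sum(keep)
  }
  labels <- matrix(0L, nr, nc)
  if (nrun == 0L) {
    return(list(labels = labels, nComponents = 0L,
                stats = data.frame(label = integer(0),
                                   pixel_count = integer(0),
                                   centroid_x = numeric(0),
                                   centroid_y = numeric(0))))
  }
  parent <- seq_len(nrun)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  # global run ids, column by column
  first_id <- integer(nc)
  k <- 0L
  for (j in seq_len(nc)) {
    first_id[j] <- k + 1L
    k <- k + length(runs_start[[j]])
  }
  off <- if (connectivity == 8) 1L else 0L
  for (j in 2:nc) {
    sa <- runs_start[[j - 1L]]; ea <- runs_end[[j - 1L]]
    sb <- runs_start[[j]]; eb <- runs_end[[j]]
    na <- length(sa); nb <- length(sb)
    if (na == 0L || nb == 0L) next
    ia <- 1L; ib <- 1L
    while (ia <= na && ib <= nb) {
      if (ea[ia] + off < sb[ib]) {
        ia <- ia + 1L
      } else if (eb[ib] + off < sa[ia]) {
        ib <- ib + 1L
      } else {
        ra <- find(first_id[j - 1L] + ia - 1L)
        rb <- find(first_id[j] + ib - 1L)
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
        # advance whichever run ends first; the other may still overlap
        if (ea[ia] + off <= eb[ib] + off) ia <- ia + 1L else ib <- ib + 1L
      }
    }
  }
  roots <- vapply(seq_len(nrun), find, integer(1))
  comp <- match(roots, sort(unique(roots)))
  nComp <- max(comp)
  npix <- numeric(nComp)
  sx <- numeric(nComp)
  sy <- numeric(nComp)
  k <- 0L
  for (j in seq_len(nc)) {
    ss <- runs_start[[j]]; ee <- runs_end[[j]]
    for (i in seq_along(ss)) {
      k <- k + 1L
      cid <- comp[k]
      len <- ee[i] - ss[i] + 1L
      labels[ss[i]:ee[i], j] <- cid
      npix[cid] <- npix[cid] + len
      sx[cid] <- sx[cid] + len * j
      sy[cid] <- sy[cid] + (ss[i] + ee[i]) * len / 2
    }
  }
  list(labels = labels, nComponents = nComp,
       stats = data.frame(label = seq_len(nComp),
                          pixel_count = as.integer(npix),
                          centroid_x = sx / npix,
                          centroid_y = sy / npix))
}

#' Detect particles on one SEM tile
#'
#' Thresholds the tile at its maximum-Renyi-entropy grey level, labels
#' connected foreground components (8-connectivity by default), converts
#' pixel counts to physical area, and applies the minimum/maximum area
#' filters (defaults 0.41 and 10000 um^2). Foreground is the bright class
#' for backscatter imagery (`foregroundPolarity = "bright"`); set `"dark"`
#' for inverted contrast.
#'
#' Entropy thresholds are unreliable on blank-like tiles: with no (or a
#' vanishing) particle phase the selected threshold can fall inside the
#' background noise mode, where chance clusters of tail pixels would
#' masquerade as particles. Detections are therefore validated per
#' component: a component is kept only when its mean grey level differs
#' from the background-class mean by at least `minClassContrast` grey
#' levels (default 30; true backscatter particle/background contrast is
#' far larger). A degenerate single-valued histogram, or a tile on which
#' no component passes the contrast check, yields an empty table with a
#' warning identifying the tile as blank-like, not an error.
#'
#' @param tile A [SemTile-class].
#' @param cfg A [SamplerConfig-class]; its `pixelSide` is ignored in favour
#'   of the tile's own scale.
#' @return `data.frame` with columns `stub_id`, `tile_index`, `particle`,
#'   `pixel_count`, `area_um2`, `centroid_x`, `centroid_y`.
#' @export
extractParticles <- function(tile, cfg = samplerConfig()) {
  stopifnot(is(tile, "SemTile"))
  empty <- data.frame(stub_id = character(0), tile_index = integer(0),
                      particle = integer(0), pixel_count = integer(0),
                      area_um2 = numeric(0), centroid_x = numeric(0),
                      centroid_y = numeric(0))
  px <- tile@pixels
  hist <- tabulate(as.vector(px) + 1L, nbins = max(256L, max(px) + 1L))
  thr <- tryCatch(renyiThreshold(hist), error = function(e) {
    if (grepl("degenerate", conditionMessage(e))) NA_real_ else stop(e)
  })
  if (is.na(thr)) {
    warning(sprintf("tile %d of stub '%s': degenerate histogram, treated as blank",
                    tile@tileIndex, tile@stubId))
    return(empty)
  }
  fg <- if (cfg@foregroundPolarity == "bright") px > thr else px <= thr
  if (!any(fg) || all(fg)) {
    warning(sprintf(
      "tile %d of stub '%s': threshold leaves a single class, treated as blank",
      tile@tileIndex, tile@stubId))
    return(empty)
  }
  lab <- labelComponents(fg, cfg@connectivity)
  st <- lab$stats
  if (nrow(st) == 0L) return(empty)
  # per-component contrast check against the background-class mean: keeps
  # genuine bright (or dark) particles, rejects chance noise clusters when
  # the threshold sits inside the background mode of a blank-like tile
  bgMean <- mean(px[!fg])
  lv <- as.vector(lab$labels)
  sel <- lv > 0L
  compMean <- rowsum(as.numeric(px)[sel], lv[sel])[, 1L] / st$pixel_count
  contrast <- if (cfg@foregroundPolarity == "bright") compMean - bgMean
              else bgMean - compMean
  st <- st[contrast >= cfg@minClassContrast, , drop = FALSE]
  if (nrow(st) == 0L) {
    warning(sprintf(
      "tile %d of stub '%s': no component exceeds the background by %g grey levels, treated as blank",
      tile@tileIndex, tile@stubId, cfg@minClassContrast))
    return(empty)
  }
  st$area_um2 <- st$pixel_count * tile@pixelSide^2
  st <- st[st$area_um2 >= cfg@minArea & st$area_um2 <= cfg@maxArea, ,
           drop = FALSE]
  if (nrow(st) == 0L) return(empty)
  data.frame(stub_id = tile@stubId, tile_index = tile@tileIndex,
             particle = seq_len(nrow(st)), pixel_count = st$pixel_count,
             area_um2 = st$area_um2, centroid_x = st$centroid_x,
             centroid_y = st$centroid_y)
}

#' Collect all particle detections of a stub
#'
#' Runs [extractParticles()] over every tile of a stub capture and
#' concatenates the detections. The analysed area is the summed tile area,
#' capped at the configured stub disc area (tiles at the stub rim image
#' some off-stub margin).
#'
#' @param x A [StubImageSet-class] or a list of [SemTile-class] tiles
#'   sharing one `stubId` and pixel scale.
#' @param cfg A [SamplerConfig-class].
#' @return A list with `particles` (the concatenated detection
#'   `data.frame`), `analyzedArea` (mm^2), `nTiles`, and `stubId`.
#' @export
collectStub <- function(x, cfg = samplerConfig()) {
  tl <- if (is(x, "StubImageSet")) x@tiles else x
  if (!length(tl)) stop("no tiles supplied")
  stopifnot(all(vapply(tl, is, logical(1), class2 = "SemTile")))
  ids <- vapply(tl, function(t) t@stubId, character(1))
  if (length(unique(ids)) != 1L)
    stop("tiles mix stub ids: ", paste(unique(ids), collapse = ", "))
  pxs <- vapply(tl, function(t) t@pixelSide, numeric(1))
  if (diff(range(pxs)) > 1e-12)
    stop("tiles mix pixel scales")
  parts <- do.call(rbind, lapply(tl, extractParticles, cfg = cfg))
  npix <- sum(vapply(tl, function(t) length(t@pixels), numeric(1)))
  area <- npix * pxs[1L]^2 / 1e6                      # um^2 -> mm^2
  stubArea <- pi * (cfg@stubDiameter / 2)^2
  list(particles = parts, analyzedArea = min(area, stubArea),
       nTiles = length(tl), stubId = ids[1L])
}
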