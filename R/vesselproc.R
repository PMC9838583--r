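#' Binary vessel mask with physical scale
#'
#' @param mask logical or 0/1 matrix.
#' @param scale_um_px micrometers per pixel (> 0).
#' @param eye_id,laterality identifiers.
#' @return object of class `vessel_mask`.
#' @export
vessel_mask <- function(mask, scale_um_px, eye_id = "eye",
                        laterality = "right") {
  stopifnot_binary(mask, "vessel mask")
  if (scale_um_px <= 0) stop("scale must be > 0", call. = FALSE)
  structure(list(mask = mask != 0, scale_um_px = scale_um_px,
                 eye_id = eye_id, laterality = laterality),
            class = "vessel_mask")
}

#' @export
print.vessel_mask <- function(x, ...) {
  cat("<vessel_mask> ", x$eye_id, " ", paste(dim(x$mask), collapse = "x"),
      " px @ ", x$scale_um_px, " um/px, ", sum(x$mask), " foreground px\n",
      sep = "")
  invisible(x)
}

#' Classical vesselness segmentation with hysteresis thresholding
#'
#' A multiscale ridge (Frangi-type) filter for dark vessels on a bright
#' background: at each Gaussian scale the Hessian eigenvalues are combined
#' into a vesselness response (blob suppression + structure strength), the
#' response is maximized over scales, and hysteresis keeps weak-threshold
#' components that contain at least one strong-threshold pixel.
#'
#' @param image grayscale matrix in `[0, 1]`.
#' @param scales_px Gaussian scales (px), one or more.
#' @param low,high hysteresis thresholds on the max-normalized vesselness.
#' @param scale_um_px physical scale carried into the result.
#' @param eye_id,laterality identifiers carried into the result.
#' @return a [vessel_mask()]; empty (with a warning) when no pixel passes.
#' @export
segment_vessels <- function(image, scales_px = c(1.5, 2.5, 4),
                            low = 0.06, high = 0.18,
                            scale_um_px = 20, eye_id = "eye",
                            laterality = "right") {
  if (!is.matrix(image)) stop("image must be a grayscale matrix", call. = FALSE)
  if (!length(scales_px)) stop("at least one scale required", call. = FALSE)
  v <- matrix(0, nrow(image), ncol(image))
  for (s in scales_px) {
    G <- as.matrix(EBImage::gblur(image, sigma = s))
    gxx <- shift_m(G, 0, 1) + shift_m(G, 0, -1) - 2 * G
    gyy <- shift_m(G, 1, 0) + shift_m(G, -1, 0) - 2 * G
    gxy <- (shift_m(G, 1, 1) + shift_m(G, -1, -1) -
              shift_m(G, 1, -1) - shift_m(G, -1, 1)) / 4
    gxx <- gxx * s^2; gyy <- gyy * s^2; gxy <- gxy * s^2
    tmp <- sqrt(((gxx - gyy) / 2)^2 + gxy^2)
    l1 <- (gxx + gyy) / 2 + tmp
    l2 <- (gxx + gyy) / 2 - tmp
    # order by |.|: lam2 = larger magnitude
    swap <- abs(l1) > abs(l2)
    lam2 <- ifelse(swap, l1, l2)
    lam1 <- ifelse(swap, l2, l1)
    rb2 <- (lam1 / pmax(abs(lam2), 1e-12))^2
    s2 <- lam1^2 + lam2^2
    cpar <- 0.5 * sqrt(max(s2))
    vs <- exp(-rb2 / (2 * 0.25)) * (1 - exp(-s2 / (2 * cpar^2)))
    vs[lam2 <= 0] <- 0   # dark ridges have positive cross-curvature
    v <- pmax(v, vs)
  }
  if (max(v) > 0) v <- v / max(v)
  weak <- v >= low
  strong <- v >= high
  if (!any(strong)) {
    warning("empty vessel mask after thresholding")
    return(vessel_mask(matrix(FALSE, nrow(image), ncol(image)), scale_um_px,
                       eye_id, laterality))
  }
  lbl <- EBImage::bwlabel(matrix(as.integer(weak), nrow(image)))
  keep <- unique(lbl[strong])
  keep <- keep[keep > 0]
  vessel_mask(matrix(lbl %in% keep, nrow(image)), scale_um_px, eye_id,
              laterality)
}

# shifted copy with edge replication; dr/dc in row/col direction
shift_m <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr) + dr, 1), nr)
  ci <- pmin(pmax(seq_len(nc) + dc, 1), nc)
  m[ri, ci, drop = FALSE]
}

#' Skeletonize a vessel mask and build its centerline graph
#'
#' Thins the mask to a one-pixel-wide skeleton (Zhang-Suen), decomposes it
#' into a graph of endpoints/junctions connected by ordered pixel chains,
#' removes endpoint-terminated spurs shorter than `spur_prune_len_mm`, merges
#' pass-through nodes left behind by pruning, and measures per-edge widths
#' from the mask's Euclidean distance transform.
#'
#' @param vm a [vessel_mask()].
#' @param spur_prune_len_mm spurs shorter than this are removed (default
#'   0.3 mm).
#' @param width_half_window moving-median half-window for width smoothing.
#' @param class_map optional arteriole/venule map (0/1/2/3, see
#'   [label_edges_from_map()]). When given, edges are labeled and each
#'   edge's widths are measured on its own class-specific mask, so a vessel
#'   of the other class running adjacent cannot inflate the distance
#'   transform.
#' @return object of class `vessel_graph`: `nodes` (data.frame id/row/col/
#'   kind), `edges` (list with from/to, ordered pixel `chain`, `length_mm`,
#'   `widths_um`, `mean_width_um`, `class`), `skeleton` (logical matrix of
#'   all edge pixels), plus scale and ids. An empty mask yields an empty
#'   graph, not an error.
#' @export
skeletonize_and_graph <- function(vm, spur_prune_len_mm = 0.3,
                                  width_half_window = 5, class_map = NULL) {
  stopifnot(inherits(vm, "vessel_mask"))
  mmpp <- vm$scale_um_px / 1000
  empty <- structure(list(nodes = data.frame(id = integer(), row = integer(),
                                             col = integer(),
                                             kind = character()),
                          edges = list(),
                          skeleton = matrix(FALSE, nrow(vm$mask),
                                            ncol(vm$mask)),
                          scale_um_px = vm$scale_um_px, eye_id = vm$eye_id,
                          laterality = vm$laterality),
                     class = "vessel_graph")
  if (!any(vm$mask)) return(empty)
  skel <- .cpp_thin(as_binary(vm$mask))
  if (!any(skel == 1L)) return(empty)
  g <- trace_graph(skel)
  if (!length(g$edges)) return(empty)
  edt <- as.matrix(EBImage::distmap(as_binary(vm$mask)))
  edt_cls <- NULL
  if (!is.null(class_map)) {
    g$eye_id <- vm$eye_id
    g <- label_edges_from_map(g, class_map)
    edt_cls <- list(
      arteriole = as.matrix(EBImage::distmap(
        matrix(as.integer(class_map == 1L | class_map == 3L),
               nrow(class_map)))),
      venule = as.matrix(EBImage::distmap(
        matrix(as.integer(class_map == 2L | class_map == 3L),
               nrow(class_map)))))
  }
  for (i in seq_along(g$edges)) {
    ch <- g$edges[[i]]$chain
    cls <- g$edges[[i]]$class %||% NA_character_
    d <- if (!is.null(edt_cls) && !is.na(cls)) {
      dc <- edt_cls[[cls]][ch]
      # crossing excisions in the class mask can zero the class EDT on a
      # skeleton pixel; fall back to the union EDT there
      ifelse(dc > 0, dc, edt[ch])
    } else edt[ch]
    w <- 2 * d * vm$scale_um_px
    g$edges[[i]]$widths_um <- smooth_median(w, width_half_window)
    g$edges[[i]]$mean_width_um <- mean(g$edges[[i]]$widths_um)
    g$edges[[i]]$length_mm <- chain_length_px(ch) * mmpp
    if (is.null(g$edges[[i]]$class)) g$edges[[i]]$class <- NA_character_
  }
  g <- prune_spurs(g, spur_prune_len_mm / mmpp, mmpp)
  sk <- matrix(FALSE, nrow(vm$mask), ncol(vm$mask))
  for (e in g$edges) sk[e$chain] <- TRUE
  structure(list(nodes = g$nodes, edges = g$edges, skeleton = sk,
                 scale_um_px = vm$scale_um_px, eye_id = vm$eye_id,
                 laterality = vm$laterality),
            class = "vessel_graph")
}

#' @export
print.vessel_graph <- function(x, ...) {
  cat("<vessel_graph> ", x$eye_id, ": ", nrow(x$nodes), " nodes (",
      sum(x$nodes$kind == "junction"), " junctions), ",
      length(x$edges), " edges\n", sep = "")
  invisible(x)
}

chain_length_px <- function(chain) {
  if (nrow(chain) < 2) return(0)
  sum(sqrt(rowSums((chain[-1, , drop = FALSE] -
                      chain[-nrow(chain), , drop = FALSE])^2)))
}

# Rutovitz crossing number: 0->1 transitions around the 8-neighbour ring.
# 1 = endpoint, 2 = ordinary path pixel (even at staircase corners), >= 3 =
# junction pixel.
crossing_number <- function(skel) {
  ring <- list(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
               c(1, 0), c(1, -1), c(0, -1), c(-1, -1))
  nbv <- lapply(ring, function(o) shift_m(skel, o[1], o[2]) *
                  border_zero(skel, o))
  A <- matrix(0L, nrow(skel), ncol(skel))
  for (k in seq_along(ring)) {
    nxt <- nbv[[if (k == length(ring)) 1 else k + 1]]
    A <- A + (nbv[[k]] == 0L & nxt == 1L)
  }
  A
}

# shift_m replicates edges; zero out the wrapped-in border for offset o
border_zero <- function(skel, o) {
  z <- matrix(1L, nrow(skel), ncol(skel))
  if (o[1] == 1) z[nrow(z), ] <- 0L
  if (o[1] == -1) z[1, ] <- 0L
  if (o[2] == 1) z[, ncol(z)] <- 0L
  if (o[2] == -1) z[, 1] <- 0L
  z
}

# Decompose a 1-px skeleton into nodes and ordered pixel chains. Junction
# pixels (crossing number >= 3) are clustered: an 8-connected component of
# junction pixels forms one node, so thick crossings do not shatter into
# micro-edges.
trace_graph <- function(skel) {
  nb <- .cpp_neighbor_count(skel)
  A <- crossing_number(skel)
  nr <- nrow(skel); nc <- ncol(skel)
  is_node_px <- skel == 1L & (A >= 3L | nb <= 1L)
  node_id <- matrix(0L, nr, nc)
  kind_vec <- character(0)
  nid <- 0L
  if (any(is_node_px)) {
    lbl <- .cpp_label8(is_node_px)
    nid <- max(lbl)
    node_id[lbl > 0] <- lbl[lbl > 0]
    npx <- which(lbl > 0, arr.ind = TRUE)
    grp <- lbl[npx]
    kind_vec <- rep("endpoint", nid)
    kind_vec[unique(grp[A[npx] >= 3L])] <- "junction"
  }
  if (nid == 0 && any(skel == 1L)) {   # pure cycle: anchor anywhere
    p <- which(skel == 1L, arr.ind = TRUE)[1, , drop = FALSE]
    node_id[p] <- 1L; nid <- 1L; kind_vec <- "junction"
    npx <- p; grp <- 1L
  }
  # cluster representative: member pixel closest to the cluster centroid
  cr <- tapply(npx[, 1], grp, mean)[as.character(seq_len(nid))]
  cc <- tapply(npx[, 2], grp, mean)[as.character(seq_len(nid))]
  d2 <- (npx[, 1] - cr[grp])^2 + (npx[, 2] - cc[grp])^2
  ord <- order(grp, d2)
  first <- ord[!duplicated(grp[ord])]
  reps <- npx[first[order(grp[first])], , drop = FALSE]
  nodes <- data.frame(id = seq_len(nid), row = reps[, 1], col = reps[, 2],
                      kind = kind_vec, stringsAsFactors = FALSE)

  tr <- .cpp_trace_chains(skel, node_id)
  edges <- lapply(seq_along(tr$from), function(i)
    list(from = tr$from[i],
         to = if (tr$to[i] > 0) tr$to[i] else NA_integer_,
         chain = tr$chains[[i]]))
  # each open chain was traced from both of its end nodes; dedupe by pixels
  seen <- new.env(hash = TRUE)
  keep <- logical(length(edges))
  for (i in seq_along(edges)) {
    ch <- edges[[i]]$chain
    inner <- ch[-c(1, nrow(ch)), , drop = FALSE]
    key <- if (nrow(inner)) {
      v <- inner[, 1] * 1e5 + inner[, 2]
      paste(min(v), max(v), nrow(inner), sum(v))
    } else {
      v <- sort(ch[, 1] * 1e5 + ch[, 2])
      paste(v, collapse = "|")
    }
    if (is.null(seen[[key]])) { seen[[key]] <- TRUE; keep[i] <- TRUE }
  }
  edges <- edges[keep]
  for (i in seq_along(edges)) edges[[i]]$id <- i
  list(nodes = nodes, edges = edges)
}

# remove endpoint-terminated edges shorter than min_len_px, then merge
# pass-through (degree-2) former junctions; iterate to a fixed point
prune_spurs <- function(g, min_len_px, mmpp) {
  repeat {
    deg <- node_degrees(g)
    spur <- vapply(g$edges, function(e) {
      endat <- c(e$from, e$to)
      any(!is.na(endat) & deg[pmax(endat, 1)] == 1 & !is.na(endat)) &&
        chain_length_px(e$chain) < min_len_px
    }, logical(1))
    # also drop dangling half-traced chains shorter than the threshold
    dangling <- vapply(g$edges, function(e) is.na(e$to) &&
                         chain_length_px(e$chain) < min_len_px, logical(1))
    spur <- spur | dangling
    if (!any(spur)) break
    g$edges <- g$edges[!spur]
    g <- merge_passthrough(g, mmpp)
    if (!length(g$edges)) break
  }
  g <- merge_passthrough(g, mmpp)
  # restrict nodes to those still referenced
  used <- unique(unlist(lapply(g$edges, function(e) c(e$from, e$to))))
  used <- used[!is.na(used)]
  g$nodes <- g$nodes[g$nodes$id %in% used, , drop = FALSE]
  deg <- node_degrees(g)
  if (nrow(g$nodes))
    g$nodes$kind <- ifelse(deg[g$nodes$id] >= 3, "junction", "endpoint")
  g
}

node_degrees <- function(g) {
  n <- max(c(0L, g$nodes$id))
  deg <- integer(n)
  for (e in g$edges) for (v in c(e$from, e$to))
    if (!is.na(v)) deg[v] <- deg[v] + 1L
  deg
}

merge_passthrough <- function(g, mmpp) {
  repeat {
    deg <- node_degrees(g)
    mid <- which(deg == 2)
    # only merge former junctions that became pass-through
    mid <- mid[g$nodes$kind[match(mid, g$nodes$id)] == "junction"]
    if (!length(mid)) return(g)
    v <- mid[1]
    inc <- which(vapply(g$edges, function(e)
      (!is.na(e$from) && e$from == v) || (!is.na(e$to) && e$to == v),
      logical(1)))
    if (length(inc) != 2) { g$nodes$kind[g$nodes$id == v] <- "endpoint"; next }
    e1 <- g$edges[[inc[1]]]; e2 <- g$edges[[inc[2]]]
    ch1 <- if (!is.na(e1$to) && e1$to == v) e1$chain else e1$chain[rev(seq_len(nrow(e1$chain))), , drop = FALSE]
    from1 <- if (!is.na(e1$to) && e1$to == v) e1$from else e1$to
    ch2 <- if (!is.na(e2$from) && e2$from == v) e2$chain else e2$chain[rev(seq_len(nrow(e2$chain))), , drop = FALSE]
    to2 <- if (!is.na(e2$from) && e2$from == v) e2$to else e2$from
    w1 <- if (!is.na(e1$to) && e1$to == v) e1$widths_um else rev(e1$widths_um)
    w2 <- if (!is.na(e2$from) && e2$from == v) e2$widths_um else rev(e2$widths_um)
    merged <- list(from = from1, to = to2,
                   chain = rbind(ch1, ch2[-1, , drop = FALSE]),
                   widths_um = c(w1, w2[-1]),
                   class = e1$class %||% e2$class,
                   id = e1$id)
    merged$mean_width_um <- mean(merged$widths_um)
    merged$length_mm <- chain_length_px(merged$chain) * mmpp
    g$edges[[inc[1]]] <- merged
    g$edges <- g$edges[-inc[2]]
  }
}

#' Per-point vessel widths along a centerline chain
#'
#' Width at a centerline point is twice the Euclidean distance from that
#' point to the nearest background pixel (distance transform of the mask),
#' converted to micrometers, then smoothed by a moving median.
#'
#' @param vm a [vessel_mask()] (or logical matrix plus `scale_um_px`).
#' @param chain two-column matrix of (row, col) skeleton pixels.
#' @param half_window moving-median half-window (points).
#' @param scale_um_px required when `vm` is a bare matrix.
#' @return numeric vector of widths (um), one per chain point.
#' @export
measure_widths <- function(vm, chain, half_window = 5, scale_um_px = NULL) {
  if (inherits(vm, "vessel_mask")) {
    mask <- vm$mask; scale_um_px <- vm$scale_um_px
  } else {
    mask <- vm != 0
    if (is.null(scale_um_px)) stop("scale_um_px required", call. = FALSE)
  }
  bad <- which(!mask[chain])
  if (length(bad))
    stop("chain pixel outside the vessel mask at (row=", chain[bad[1], 1],
         ", col=", chain[bad[1], 2], ")", call. = FALSE)
  edt <- as.matrix(EBImage::distmap(as_binary(mask)))
  smooth_median(2 * edt[chain] * scale_um_px, half_window)
}

#' Label graph edges as arteriole or venule from a class map
#'
#' Each edge takes the majority label of the class-map values along its
#' pixel chain (0 = unlabeled background, 1 = arteriole, 2 = venule, 3 =
#' both at crossings); edges whose pixels are all unlabeled stay `NA`.
#'
#' @param graph a `vessel_graph`.
#' @param class_map integer matrix (0/1/2/3), e.g. the rasterizer's truth
#'   map.
#' @return the graph with `class` filled on each edge.
#' @export
label_edges_from_map <- function(graph, class_map) {
  for (i in seq_along(graph$edges)) {
    v <- class_map[graph$edges[[i]]$chain]
    votes <- c(arteriole = sum(v == 1L | v == 3L),
               venule = sum(v == 2L | v == 3L))
    if (any(votes > 0))
      graph$edges[[i]]$class <- names(votes)[which.max(votes)]
  }
  graph
}

#' Select the most prominent unbroken path per quadrant and vessel class
#'
#' Candidate paths start at disc-proximal nodes (nodes within 0.75 disc
#' diameters of the disc center; all endpoints if none) and are traversed
#' distally, crossing junctions onto the same-class edge whose mean width is
#' closest to the current edge (width continuity). For each
#' (quadrant, class) the candidate whose arclength-majority lies in that
#' quadrant and maximizes `total arclength x mean width` is selected; ties
#' break by greater mean width, then lowest starting pixel row, then column.
#' Quadrants without candidates yield no entry.
#'
#' @param graph a `vessel_graph` with per-edge `class` labels.
#' @param quadrants character matrix from [quadrant_partition()].
#' @param disc list with `center` (mm) and `diameter_mm`.
#' @param overrides optional data.frame (quadrant, class, edge_ids =
#'   semicolon-separated edge ids) forcing the operator's path choice.
#' @param width_jump_frac traversal stops when the best same-class
#'   continuation differs in mean width by more than this fraction (a break
#'   in prominence, e.g. stepping onto a crossing vessel).
#' @param outward traversal stops rather than turn back toward the disc.
#' @return named list (`"<quadrant>_<class>"`) of `vessel_path` objects:
#'   each has `points` (x_mm, y_mm, width_um, s_mm ordered disc-proximal to
#'   distal), `class`, `quadrant`, `length_mm`, `mean_width_um`.
#' @export
select_quadrant_paths <- function(graph, quadrants, disc, overrides = NULL,
                                  width_jump_frac = 0.15, outward = TRUE) {
  if (!length(graph$edges)) return(list())
  unlabeled <- which(vapply(graph$edges, function(e) is.na(e$class),
                            logical(1)))
  if (length(unlabeled))
    stop("unlabeled edges: ", paste(vapply(graph$edges[unlabeled],
                                           function(e) e$id, numeric(1)),
                                    collapse = ", "), call. = FALSE)
  mmpp <- graph$scale_um_px / 1000
  nd <- graph$nodes
  dist_disc <- sqrt((px_to_mm(nd$col, graph$scale_um_px) -
                       disc$center[1])^2 +
                    (px_to_mm(nd$row, graph$scale_um_px) -
                       disc$center[2])^2)
  roots <- nd$id[dist_disc <= 0.75 * disc$diameter_mm]
  if (!length(roots)) roots <- nd$id[nd$kind == "endpoint"]
  if (!length(roots)) roots <- nd$id
  node_disc_dist <- rep(NA_real_, max(nd$id))
  node_disc_dist[nd$id] <- dist_disc

  incident <- vector("list", max(nd$id))
  for (i in seq_along(graph$edges)) {
    e <- graph$edges[[i]]
    for (v in unique(c(e$from, e$to)))
      if (!is.na(v)) incident[[v]] <- c(incident[[v]], i)
  }

  candidates <- list()
  for (r in sort(roots)) {
    for (ei in incident[[r]]) {
      path_edges <- integer(0)
      orient <- logical(0)
      cur_node <- r; cur_ei <- ei
      repeat {
        e <- graph$edges[[cur_ei]]
        fwd <- !is.na(e$from) && e$from == cur_node
        path_edges <- c(path_edges, cur_ei)
        orient <- c(orient, fwd)
        nxt_node <- if (fwd) e$to else e$from
        if (is.na(nxt_node)) break
        nxt <- setdiff(incident[[nxt_node]], path_edges)
        nxt <- nxt[vapply(graph$edges[nxt], function(x)
          identical(x$class, e$class), logical(1))]
        if (outward) {
          # only continuations that do not turn back toward the disc
          d_here <- node_disc_dist[nxt_node]
          nxt <- nxt[vapply(graph$edges[nxt], function(x) {
            other <- if (!is.na(x$from) && x$from == nxt_node) x$to else
              x$from
            is.na(other) || node_disc_dist[other] > d_here - 0.2
          }, logical(1))]
        }
        if (!length(nxt)) break
        dw <- vapply(graph$edges[nxt], function(x)
          abs(x$mean_width_um - e$mean_width_um), numeric(1))
        if (min(dw) > width_jump_frac * e$mean_width_um) break
        cur_ei <- nxt[which.min(dw)]
        cur_node <- nxt_node
      }
      candidates[[length(candidates) + 1L]] <-
        build_path(graph, path_edges, orient, mmpp)
    }
  }

  selected <- list()
  if (!is.null(overrides) && nrow(overrides)) {
    for (i in seq_len(nrow(overrides))) {
      ids <- as.integer(strsplit(as.character(overrides$edge_ids[i]),
                                 ";")[[1]])
      eidx <- match(ids, vapply(graph$edges, function(e) e$id, numeric(1)))
      orient <- rep(TRUE, length(eidx))
      # orient consecutive edges head-to-tail
      if (length(eidx) > 1) {
        for (k in 2:length(eidx)) {
          prev_end <- if (orient[k - 1]) graph$edges[[eidx[k - 1]]]$to else
            graph$edges[[eidx[k - 1]]]$from
          orient[k] <- identical(graph$edges[[eidx[k]]]$from, prev_end)
        }
      }
      p <- build_path(graph, eidx, orient, mmpp)
      p$quadrant <- as.character(overrides$quadrant[i])
      p$class <- as.character(overrides$class[i])
      selected[[paste(p$quadrant, p$class, sep = "_")]] <- p
    }
  }

  for (p in candidates) {
    q <- majority_quadrant(p, quadrants, graph$scale_um_px)
    p$quadrant <- q
    key <- paste(q, p$class, sep = "_")
    if (!is.null(selected[[key]])) {
      if (!better_path(p, selected[[key]])) next
      if (!is.null(overrides) && nrow(overrides) &&
          any(overrides$quadrant == q & overrides$class == p$class)) next
    }
    selected[[key]] <- p
  }
  selected
}

build_path <- function(graph, eidx, orient, mmpp) {
  px <- NULL; w <- NULL; jidx <- integer(0)
  for (k in seq_along(eidx)) {
    e <- graph$edges[[eidx[k]]]
    ch <- e$chain; wk <- e$widths_um
    if (!orient[k]) {
      ch <- ch[rev(seq_len(nrow(ch))), , drop = FALSE]
      wk <- rev(wk)
    }
    if (!is.null(px)) {
      jidx <- c(jidx, nrow(px))          # internal junction position
      ch <- ch[-1, , drop = FALSE]; wk <- wk[-1]
    }
    px <- rbind(px, ch); w <- c(w, wk)
  }
  # arclength along a smoothed copy of the chain: raw 8-connected pixel
  # chains overstate curve length (staircase + thinning ridge jitter),
  # which would bias width-gradient slopes toward zero
  sr <- smooth_ma(px[, 1], 9); sc <- smooth_ma(px[, 2], 9)
  steps <- sqrt(diff(sr)^2 + diff(sc)^2)
  steps[steps <= 0] <- 1e-6
  s <- c(0, cumsum(steps)) * mmpp
  structure(list(points = data.frame(
    x_mm = px_to_mm(px[, 2], mmpp * 1000),
    y_mm = px_to_mm(px[, 1], mmpp * 1000),
    width_um = w, s_mm = s),
    chain = px,
    class = graph$edges[[eidx[1]]]$class, quadrant = NA_character_,
    length_mm = max(s), mean_width_um = mean(w),
    px_mm = mmpp,
    junction_s_mm = s[jidx],
    edge_ids = vapply(graph$edges[eidx], function(e) e$id, numeric(1)),
    eye_id = graph$eye_id),
    class = "vessel_path")
}

#' @export
print.vessel_path <- function(x, ...) {
  cat(sprintf("<vessel_path> %s %s: %.2f mm, mean width %.1f um, %d points\n",
              x$quadrant, x$class, x$length_mm, x$mean_width_um,
              nrow(x$points)))
  invisible(x)
}

majority_quadrant <- function(p, quadrants, scale_um_px) {
  ch <- p$chain
  steps <- c(0, sqrt(rowSums((ch[-1, , drop = FALSE] -
                                ch[-nrow(ch), , drop = FALSE])^2)))
  labs <- quadrants[ch]
  tot <- tapply(steps, labs, sum)
  names(tot)[which.max(tot)]
}

path_score <- function(p) p$length_mm * p$mean_width_um

# deterministic preference: score, then mean width, then lowest starting
# pixel row, then column
better_path <- function(a, b) {
  if (abs(path_score(a) - path_score(b)) > 1e-9)
    return(path_score(a) > path_score(b))
  if (abs(a$mean_width_um - b$mean_width_um) > 1e-9)
    return(a$mean_width_um > b$mean_width_um)
  if (a$chain[1, 1] != b$chain[1, 1]) return(a$chain[1, 1] < b$chain[1, 1])
  a$chain[1, 2] < b$chain[1, 2]
}

#' Apply operator mask edits (erase/fill polygons)
#'
#' Stand-in for manual operator correction of the automatic segmentation:
#' each GeoJSON polygon feature carries an `action` property, `"erase"` or
#' `"fill"`, applied in file order.
#'
#' @param vm a [vessel_mask()].
#' @param edits_path GeoJSON file of polygon features (coordinates in mm).
#' @return the edited `vessel_mask`.
#' @export
apply_mask_edits <- function(vm, edits_path) {
  fc <- jsonlite::read_json(edits_path)
  for (f in fc$features) {
    if (!identical(f$geometry$type, "Polygon")) next
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]], unlist))
    pm <- polygon_mask(ring[-nrow(ring), , drop = FALSE], nrow(vm$mask),
                       vm$scale_um_px)
    act <- f$properties$action
    if (identical(act, "erase")) vm$mask[pm] <- FALSE
    else if (identical(act, "fill")) vm$mask[pm] <- TRUE
    else stop("unknown mask edit action: ", act, call. = FALSE)
  }
  vm
}
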