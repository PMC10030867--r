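# Skeletonization of the vessel mask (topology-preserving thinning), the
# midline graph (branch nodes, endpoints, traced segments) and the
# vascular-net topology metrics.

# one Zhang-Suen subiteration; bw is logical with a FALSE border guaranteed
zs_subiter <- function(bw, step) {
  nr <- nrow(bw); nc <- ncol(bw)
  sh <- function(dr, dc) {
    m <- matrix(FALSE, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    m[rs, cs] <- bw[rs - dr, cs - dc]
    m
  }
  p2 <- sh(-1, 0); p3 <- sh(-1, 1); p4 <- sh(0, 1); p5 <- sh(1, 1)
  p6 <- sh(1, 0); p7 <- sh(1, -1); p8 <- sh(0, -1); p9 <- sh(-1, -1)
  B <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
  seqs <- list(p2, p3, p4, p5, p6, p7, p8, p9, p2)
  A <- matrix(0L, nr, nc)
  for (i in 1:8) A <- A + (!seqs[[i]] & seqs[[i + 1]])
  if (step == 1L) {
    cond <- bw & B >= 2 & B <= 6 & A == 1 &
      !(p2 & p4 & p6) & !(p4 & p6 & p8)
  } else {
    cond <- bw & B >= 2 & B <= 6 & A == 1 &
      !(p2 & p4 & p8) & !(p2 & p6 & p8)
  }
  bw & !cond
}

# Zhang-Suen thinning to a 1-px-wide 8-connected skeleton
thin_mask <- function(mask) {
  bw <- mask
  bw[1, ] <- FALSE; bw[nrow(bw), ] <- FALSE
  bw[, 1] <- FALSE; bw[, ncol(bw)] <- FALSE
  repeat {
    b1 <- zs_subiter(bw, 1L)
    b2 <- zs_subiter(b1, 2L)
    if (identical(b2, bw)) break
    bw <- b2
  }
  bw
}

# 8-neighbor degree of each skeleton pixel
skel_degree <- function(bw) {
  k <- matrix(1, 3, 3); k[2, 2] <- 0
  round(xcorr2(matrix(as.numeric(bw), nrow(bw), ncol(bw)), k)) * bw
}

# Rutovitz crossing number: 0->1 transitions around the 8-neighborhood.
# Robust branch/end classification on 8-connected skeletons, where diagonal
# staircases inflate the raw neighbor count.
skel_crossings <- function(bw) {
  nr <- nrow(bw); nc <- ncol(bw)
  sh <- function(dr, dc) {
    m <- matrix(FALSE, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    m[rs, cs] <- bw[rs - dr, cs - dc]
    m
  }
  seqs <- list(sh(-1, 0), sh(-1, 1), sh(0, 1), sh(1, 1),
               sh(1, 0), sh(1, -1), sh(0, -1), sh(-1, -1))
  seqs[[9]] <- seqs[[1]]
  A <- matrix(0L, nr, nc)
  for (i in 1:8) A <- A + (!seqs[[i]] & seqs[[i + 1]])
  A * bw
}

# trace the skeleton graph: junction clusters + endpoints as nodes,
# degree-2 chains as segments
trace_skeleton <- function(bw) {
  deg <- skel_degree(bw)
  cross <- skel_crossings(bw)
  branch <- bw & cross >= 3
  ends <- bw & deg == 1
  node_id <- matrix(0L, nrow(bw), ncol(bw))
  nodes <- list()
  nid <- 0L
  if (any(branch)) {
    # merge branch pixels within a few px into one junction: thinning often
    # resolves one anatomical bifurcation into 2-3 nearby branch pixels
    merged <- dilate_disc(branch, 2)
    lab <- EBImage::bwlabel(matrix(as.numeric(merged), nrow(bw), ncol(bw)))
    lab <- as.matrix(EBImage::imageData(lab)) * branch
    for (l in seq_len(max(lab))) {
      px <- which(lab == l, arr.ind = TRUE)
      if (!nrow(px)) next
      nid <- nid + 1L
      node_id[px] <- nid
      nodes[[nid]] <- list(id = nid, type = "branch",
                           row = mean(px[, 1]), col = mean(px[, 2]))
    }
  }
  ep <- which(ends, arr.ind = TRUE)
  for (i in seq_len(nrow(ep))) {
    nid <- nid + 1L
    node_id[ep[i, , drop = FALSE]] <- nid
    nodes[[nid]] <- list(id = nid, type = "end",
                         row = ep[i, 1], col = ep[i, 2])
  }
  nbr <- rbind(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
               c(1, 0), c(1, -1), c(0, -1), c(-1, -1))
  visited <- matrix(FALSE, nrow(bw), ncol(bw))
  segments <- list()
  walk <- function(start, first) {
    path <- rbind(start, first)
    prev <- start; cur <- first
    while (node_id[cur[1], cur[2]] == 0L) {
      visited[cur[1], cur[2]] <<- TRUE
      nxt <- NULL
      for (d in seq_len(8)) {
        q <- cur + nbr[d, ]
        if (q[1] < 1 || q[1] > nrow(bw) || q[2] < 1 || q[2] > ncol(bw)) next
        if (!bw[q[1], q[2]]) next
        if (all(q == prev)) next
        if (node_id[q[1], q[2]] == 0L && visited[q[1], q[2]]) next
        if (node_id[q[1], q[2]] != 0L && nrow(path) == 2 &&
            node_id[q[1], q[2]] == node_id[start[1], start[2]]) next
        nxt <- q; break
      }
      if (is.null(nxt)) break
      path <- rbind(path, nxt)
      prev <- cur; cur <- nxt
    }
    path
  }
  node_px <- which(node_id != 0L, arr.ind = TRUE)
  for (i in seq_len(nrow(node_px))) {
    p <- node_px[i, ]
    for (d in seq_len(8)) {
      q <- p + nbr[d, ]
      if (q[1] < 1 || q[1] > nrow(bw) || q[2] < 1 || q[2] > ncol(bw)) next
      if (!bw[q[1], q[2]]) next
      qid <- node_id[q[1], q[2]]
      if (qid != 0L) {
        # direct node-node adjacency: record once, only across clusters
        pid <- node_id[p[1], p[2]]
        if (qid > pid) {
          segments[[length(segments) + 1L]] <- rbind(p, q)
        }
        next
      }
      if (visited[q[1], q[2]]) next
      path <- walk(p, q)
      segments[[length(segments) + 1L]] <- path
    }
  }
  if (!length(segments) && any(bw & !visited & node_id == 0L)) {
    # isolated cycle: open it at an arbitrary pixel
    st <- which(bw & node_id == 0L, arr.ind = TRUE)[1, ]
    for (d in seq_len(8)) {
      q <- st + nbr[d, ]
      if (q[1] >= 1 && q[1] <= nrow(bw) && q[2] >= 1 && q[2] <= ncol(bw) &&
          bw[q[1], q[2]]) {
        visited[st[1], st[2]] <- TRUE
        segments[[1]] <- walk(st, q)
        break
      }
    }
  }
  # drop duplicate traces of the same chain (walked from both end nodes)
  if (length(segments) > 1) {
    keys <- vapply(segments, function(s) {
      k1 <- paste(apply(s, 1, paste, collapse = ","), collapse = ";")
      k2 <- paste(apply(s[nrow(s):1, , drop = FALSE], 1, paste, collapse = ","),
                  collapse = ";")
      min(k1, k2)
    }, "")
    segments <- segments[!duplicated(keys)]
  }
  seg_len <- function(path) {
    n <- nrow(path)
    if (n < 2) return(0)
    if (n <= 4) {
      st <- abs(path[-1, , drop = FALSE] - path[-n, , drop = FALSE])
      return(sum(ifelse(st[, 1] + st[, 2] == 2, sqrt(2), 1)))
    }
    # chord-subsampled arc length: raw 8-connected stepping overestimates
    # the length of digitized curves by several percent
    idx <- unique(c(seq(1, n, by = 3), n))
    p <- path[idx, , drop = FALSE]
    sum(sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2)))
  }
  segs <- lapply(seq_along(segments), function(i) {
    p <- segments[[i]]
    list(id = i, path = unname(p), length = seg_len(p),
         from = node_id[p[1, 1], p[1, 2]],
         to = node_id[p[nrow(p), 1], p[nrow(p), 2]])
  })
  # drop short connectors internal to one merged junction
  keep <- vapply(segs, function(s)
    !(s$from > 0 && s$from == s$to && s$length < 8), TRUE)
  segs <- segs[keep]
  for (i in seq_along(segs)) segs[[i]]$id <- i
  list(nodes = nodes, segments = segs, node_id = node_id)
}

#' Skeletonize a vessel mask into a midline graph
#'
#' Topology-preserving (Zhang-Suen) thinning to a 1-px-wide centerline,
#' classification of skeleton pixels by 8-neighborhood degree (adjacent
#' branch pixels merged into one junction node), segment tracing between
#' nodes with arc length (diagonal steps weigh sqrt(2)), and pruning of
#' terminal spurs shorter than `prune_px` (thinning artifacts of wide
#' tubes).
#'
#' @param mask logical matrix, TRUE = vessel.
#' @param prune_px prune endpoint-to-junction segments shorter than this
#'   (default 8; set 0 to disable).
#' @return A `vessel_skeleton`: list with `pixels` (logical matrix),
#'   `nodes` (list: id, type `"branch"`/`"end"`, row, col), `segments`
#'   (list: id, path (m x 2, row/col 1-based), length, from, to).
#' @export
skeletonize <- function(mask, prune_px = 8) {
  if (!any(mask)) {
    return(structure(list(pixels = mask & FALSE, nodes = list(),
                          segments = list()), class = "vessel_skeleton"))
  }
  bw <- thin_mask(mask)
  for (pass in 1:4) {
    gr <- trace_skeleton(bw)
    if (prune_px <= 0) break
    types <- vapply(gr$nodes, function(n) n$type, "")
    spur <- vapply(gr$segments, function(s) {
      et <- c(if (s$from > 0) types[s$from] else "none",
              if (s$to > 0) types[s$to] else "none")
      s$length < prune_px && sum(et == "end") == 1 && sum(et == "branch") == 1
    }, TRUE)
    if (!any(spur)) break
    for (s in gr$segments[spur]) {
      drop <- s$path
      # keep the junction-side pixel(s)
      keep_node <- if (s$from > 0 && types[s$from] == "branch") 1L else nrow(drop)
      drop <- drop[-keep_node, , drop = FALSE]
      bw[drop] <- FALSE
    }
    bw <- thin_mask(bw)
  }
  gr <- trace_skeleton(bw)
  if (length(gr$segments) > 1) {
    # sub-3-px remnants of junction clusters carry no vessel geometry
    keep <- vapply(gr$segments, function(s) s$length >= 3, TRUE)
    if (any(keep)) gr$segments <- gr$segments[keep]
    for (i in seq_along(gr$segments)) gr$segments[[i]]$id <- i
  }
  structure(list(pixels = bw, nodes = gr$nodes, segments = gr$segments),
            class = "vessel_skeleton")
}

#' @export
print.vessel_skeleton <- function(x, ...) {
  nb <- sum(vapply(x$nodes, function(n) n$type == "branch", TRUE))
  ne <- sum(vapply(x$nodes, function(n) n$type == "end", TRUE))
  cat(sprintf("vessel_skeleton: %d px, %d branch node(s), %d endpoint(s), %d segment(s)\n",
              sum(x$pixels), nb, ne, length(x$segments)))
  invisible(x)
}

#' Topology metrics of the vascular net
#'
#' Total and per-segment arc length, branchiness (branch nodes per unit
#' total length), compactness (isoperimetric ratio 4 pi area / perimeter^2
#' of the mask) and per-segment tortuosity (arc length / endpoint chord
#' length). Segments of zero length or zero chord are excluded with a
#' warning.
#'
#' @param skeleton a `vessel_skeleton`.
#' @param mask the vessel mask the skeleton came from.
#' @return list with `total_length`, `segment_lengths`, `branchiness`,
#'   `compactness`, `tortuosity` (per segment), `n_branch_nodes`,
#'   `n_endpoints`, `n_segments`.
#' @export
topology_metrics <- function(skeleton, mask) {
  segs <- skeleton$segments
  lens <- vapply(segs, function(s) s$length, 0)
  ok <- lens > 0
  if (any(!ok)) warning("excluding ", sum(!ok), " zero-length segment(s)")
  tor <- vapply(segs[ok], function(s) {
    chord <- sqrt(sum((s$path[nrow(s$path), ] - s$path[1, ])^2))
    if (chord == 0) return(NA_real_)
    s$length / chord
  }, 0)
  if (anyNA(tor)) {
    warning("excluding ", sum(is.na(tor)), " zero-chord segment(s)")
    tor <- tor[!is.na(tor)]
  }
  nb <- sum(vapply(skeleton$nodes, function(n) n$type == "branch", TRUE))
  ne <- sum(vapply(skeleton$nodes, function(n) n$type == "end", TRUE))
  total <- sum(lens[ok])
  area <- sum(mask)
  per <- mask_perimeter(mask)
  list(total_length = total,
       segment_lengths = lens[ok],
       branchiness = if (total > 0) nb / total else 0,
       compactness = if (per > 0) 4 * pi * area / per^2 else 0,
       tortuosity = tor,
       n_branch_nodes = nb, n_endpoints = ne, n_segments = sum(ok))
}

# total mask perimeter from labeled shape features
mask_perimeter <- function(mask) {
  if (!any(mask)) return(0)
  lab <- EBImage::bwlabel(matrix(as.numeric(mask), nrow(mask), ncol(mask)))
  fs <- EBImage::computeFeatures.shape(lab)
  sum(fs[, "s.perimeter"])
}
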