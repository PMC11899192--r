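# Centerline-loop extraction from a unit-width skeleton.
#
# The skeleton is viewed as a graph on its pixels with 8-neighbor edges.
# Diagonal "shortcut" edges that skip over an edge-connected corner pixel are
# dropped first (so a thin digital curve becomes a proper path/cycle graph),
# spur branches are pruned by iterative removal of degree-1 pixels, and the
# longest remaining simple cycle is returned as the centerline loop. If
# pruning consumes the whole graph the ring is open (a broken, C-shaped
# wall); the longest simple path is then returned flagged `is_closed = FALSE`
# rather than failing, since walls broken by thinning are precisely the
# interesting ones.

build_skeleton_graph <- function(skel) {
  nr <- nrow(skel); nc <- ncol(skel)
  idx <- which(skel == 1L)
  n <- length(idx)
  if (n == 0L) stop("empty skeleton", call. = FALSE)
  rr <- ((idx - 1L) %% nr) + 1L
  cc <- ((idx - 1L) %/% nr) + 1L
  idm <- matrix(0L, nr, nc)
  idm[idx] <- seq_len(n)
  at <- function(r, c) {
    ok <- r >= 1L & r <= nr & c >= 1L & c <= nc
    out <- integer(length(r))
    out[ok] <- idm[cbind(r[ok], c[ok])]
    out
  }
  ea <- integer(0); eb <- integer(0); ew <- numeric(0)
  add_edges <- function(nb, w) {
    keep <- nb > 0L
    ea <<- c(ea, seq_len(n)[keep]); eb <<- c(eb, nb[keep])
    ew <<- c(ew, rep(w, sum(keep)))
  }
  add_edges(at(rr, cc + 1L), 1)       # east
  add_edges(at(rr + 1L, cc), 1)       # south
  # diagonals, skipping shortcuts across an edge-connected corner pixel
  se <- at(rr + 1L, cc + 1L)
  se[at(rr + 1L, cc) > 0L | at(rr, cc + 1L) > 0L] <- 0L
  add_edges(se, sqrt(2))
  sw <- at(rr + 1L, cc - 1L)
  sw[at(rr + 1L, cc) > 0L | at(rr, cc - 1L) > 0L] <- 0L
  add_edges(sw, sqrt(2))

  adj <- vector("list", n)
  wts <- vector("list", n)
  if (length(ea)) {
    ord_a <- split(seq_along(ea), factor(ea, levels = seq_len(n)))
    ord_b <- split(seq_along(eb), factor(eb, levels = seq_len(n)))
    for (v in seq_len(n)) {
      ia <- ord_a[[v]]; ib <- ord_b[[v]]
      adj[[v]] <- c(eb[ia], ea[ib])
      wts[[v]] <- c(ew[ia], ew[ib])
      o <- order(adj[[v]])
      adj[[v]] <- adj[[v]][o]; wts[[v]] <- wts[[v]][o]
    }
  }
  list(n = n, row = rr, col = cc, adj = adj, wts = wts)
}

prune_spurs <- function(g) {
  alive <- rep(TRUE, g$n)
  deg <- vapply(seq_len(g$n), function(v) length(g$adj[[v]]), integer(1))
  queue <- which(deg == 1L)
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    if (!alive[v] || deg[v] > 1L) next
    alive[v] <- FALSE
    for (u in g$adj[[v]]) {
      if (alive[u]) {
        deg[u] <- deg[u] - 1L
        if (deg[u] == 1L) queue <- c(queue, u)
      }
    }
    deg[v] <- 0L
  }
  alive
}

# step weight between two adjacent pixels
step_w <- function(g, a, b) g$wts[[a]][match(b, g$adj[[a]])]

# Longest simple path in a forest via double sweep (exact on trees).
tree_longest_path <- function(g) {
  far <- function(start) {
    dist <- rep(-1, g$n); parent <- rep(0L, g$n)
    dist[start] <- 0
    queue <- start
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- g$adj[[v]]; w <- g$wts[[v]]
      for (k in seq_along(nb)) {
        u <- nb[k]
        if (dist[u] < 0) {
          dist[u] <- dist[v] + w[k]; parent[u] <- v
          queue <- c(queue, u)
        }
      }
    }
    list(dist = dist, parent = parent)
  }
  best <- NULL; best_len <- -1
  seen <- rep(FALSE, g$n)
  for (s in seq_len(g$n)) {
    if (seen[s]) next
    f1 <- far(s)
    comp <- which(f1$dist >= 0)
    seen[comp] <- TRUE
    u <- comp[which.max(f1$dist[comp])]
    f2 <- far(u)
    v <- comp[which.max(f2$dist[comp])]
    if (f2$dist[v] > best_len) {
      best_len <- f2$dist[v]
      path <- v
      while (path[1] != u) path <- c(f2$parent[path[1]], path)
      best <- path
    }
  }
  list(path = best, length = best_len)
}

# Longest simple cycle among the surviving (all-degree >= 2) pixels, by
# contracting degree-2 chains between junction pixels and searching the small
# junction-level multigraph exhaustively. Ties broken by first find in
# deterministic scan order.
longest_cycle <- function(g, alive) {
  deg <- vapply(seq_len(g$n), function(v) sum(alive[g$adj[[v]]]), integer(1))
  deg[!alive] <- 0L
  junctions <- which(alive & deg >= 3L)
  is_j <- rep(FALSE, g$n); is_j[junctions] <- TRUE

  best_path <- NULL; best_len <- -1
  consider <- function(path, len) {
    if (len > best_len) { best_len <<- len; best_path <<- path }
  }

  # pure degree-2 cycles not touching any junction
  visited <- rep(FALSE, g$n)
  visited[junctions] <- TRUE
  for (s in seq_len(g$n)) {
    if (!alive[s] || visited[s]) next
    # walk the cycle
    path <- s; len <- 0
    prev <- 0L; cur <- s
    repeat {
      visited[cur] <- TRUE
      nb <- g$adj[[cur]][alive[g$adj[[cur]]]]
      nxt <- nb[nb != prev]
      if (length(nxt) == 0L) break           # isolated stub (shouldn't occur)
      if (any(is_j[nb])) { len <- -1; break }  # chain handled via junctions
      nxt <- nxt[1]
      len <- len + step_w(g, cur, nxt)
      if (nxt == s) { consider(path, len); break }
      path <- c(path, nxt)
      prev <- cur; cur <- nxt
    }
  }

  if (length(junctions)) {
    # collect arcs between junctions (or junction self-loops)
    arcs <- list()
    seen_arc <- character(0)
    for (j in junctions) {
      for (nb1 in g$adj[[j]][alive[g$adj[[j]]]]) {
        pixels <- j; len <- step_w(g, j, nb1)
        prev <- j; cur <- nb1
        while (!is_j[cur]) {
          pixels <- c(pixels, cur)
          nbs <- g$adj[[cur]][alive[g$adj[[cur]]]]
          nxt <- nbs[nbs != prev][1]
          len <- len + step_w(g, cur, nxt)
          prev <- cur; cur <- nxt
        }
        pixels <- c(pixels, cur)
        key <- paste(min(j, cur), max(j, cur),
                     paste(range(pixels), collapse = ","), length(pixels),
                     sum(pixels), round(len, 9), sep = "|")
        if (!(key %in% seen_arc)) {
          seen_arc <- c(seen_arc, key)
          arcs[[length(arcs) + 1L]] <- list(u = j, v = cur,
                                            pixels = pixels, len = len)
        }
      }
    }
    # DFS over the junction multigraph for the longest simple cycle
    n_arcs <- length(arcs)
    used <- rep(FALSE, n_arcs)
    visited_j <- rep(FALSE, g$n)
    dfs <- function(start, cur, len, arc_seq) {
      for (ai in seq_len(n_arcs)) {
        if (used[ai]) next
        a <- arcs[[ai]]
        nxt <- if (a$u == cur) a$v else if (a$v == cur) a$u else next
        if (nxt == start && (length(arc_seq) >= 1L || a$u == a$v)) {
          total <- len + a$len
          if (total > best_len) {
            pix <- integer(0)
            at <- start
            for (k in c(arc_seq, ai)) {
              arc <- arcs[[k]]
              seg <- arc$pixels
              if (seg[1] != at) seg <- rev(seg)
              pix <- c(pix, seg[-length(seg)])
              at <- if (arc$u == at) arc$v else arc$u
            }
            best_len <<- total; best_path <<- pix
          }
          next
        }
        if (nxt == start || visited_j[nxt]) next
        used[ai] <<- TRUE; visited_j[nxt] <<- TRUE
        dfs(start, nxt, len + a$len, c(arc_seq, ai))
        used[ai] <<- FALSE; visited_j[nxt] <<- FALSE
      }
    }
    for (j in junctions) {
      dfs(j, j, 0, integer(0))
      visited_j[j] <- TRUE   # cycles through j already enumerated
    }
    # self-loop arcs are covered by the DFS (u == v closes immediately)
  }
  if (is.null(best_path)) return(NULL)
  list(path = best_path, length = best_len)
}

#' Extract the centerline loop from a skeleton
#'
#' Prunes spur branches (iterative removal of degree-1 skeleton pixels) and
#' returns the longest remaining simple cycle as an ordered closed pixel
#' path. If pruning consumes every pixel, the skeleton is an open curve; the
#' longest simple path over the unpruned skeleton is returned with
#' `is_closed = FALSE` and a warning.
#'
#' @param skel skeleton matrix from [skeletonize_mask()] (0/1, optional
#'   `pixel_spacing` attribute).
#' @return object of class `centerline_loop`: list with `pixel_path` (n x 2
#'   matrix of row/col grid coordinates, 0-based), `is_closed`, and
#'   `length_mm` when spacing is known (`NA` otherwise).
#' @export
extract_centerline_loop <- function(skel) {
  sp <- attr(skel, "pixel_spacing")
  g <- build_skeleton_graph(skel)
  alive <- prune_spurs(g)
  if (!any(alive)) {
    warning("open ring: skeleton has no cycle; using longest path",
            call. = FALSE)
    lp <- tree_longest_path(g)
    path <- lp$path; closed <- FALSE
  } else {
    cyc <- longest_cycle(g, alive)
    if (is.null(cyc)) {
      warning("open ring: no cycle found after pruning; using longest path",
              call. = FALSE)
      lp <- tree_longest_path(g)
      path <- lp$path; closed <- FALSE
    } else {
      path <- cyc$path; closed <- TRUE
    }
  }
  loop <- structure(
    list(pixel_path = cbind(row = g$row[path] - 1L, col = g$col[path] - 1L),
         is_closed = closed,
         length_mm = NA_real_),
    class = "centerline_loop")
  if (!is.null(sp)) loop$length_mm <- centerline_length(loop, sp)
  loop
}

#' Physical length of a centerline loop
#'
#' Sums unit steps between edge-neighbors and `sqrt(2)` steps between
#' diagonal neighbors along the path, times the (isotropic) pixel spacing;
#' the closing step is included for closed loops.
#'
#' @param loop a [extract_centerline_loop()] result.
#' @param pixel_spacing isotropic pixel spacing in mm (scalar or length-2).
#' @return length in mm.
#' @export
centerline_length <- function(loop, pixel_spacing) {
  sp <- require_isotropic(normalize_spacing(pixel_spacing))
  p <- loop$pixel_path
  if (nrow(p) < 2L) return(0)
  d <- abs(diff(p))
  steps <- ifelse(rowSums(d) == 2L, sqrt(2), 1)
  total <- sum(steps)
  if (isTRUE(loop$is_closed)) {
    dc <- abs(p[1, ] - p[nrow(p), ])
    total <- total + if (sum(dc) == 2L) sqrt(2) else 1
  }
  sp * total
}

#' @export
print.centerline_loop <- function(x, ...) {
  cat("<centerline_loop> ", nrow(x$pixel_path), " pixels, ",
      if (x$is_closed) "closed" else "open (flagged)",
      if (!is.na(x$length_mm)) sprintf(", %.2f mm", x$length_mm) else "",
      "\n", sep = "")
  invisible(x)
}
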