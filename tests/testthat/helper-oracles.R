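# Independent oracles used to cross-check the package's
# implementations on small instances. These deliberately share no code
# with the package: the cluster-count oracle sweeps density thresholds
# with brute-force connected components (no linkage machinery), and
# the matching oracle enumerates every (prediction, event) pair.

# Exhaustive density-connectivity clustering: build the
# mutual-reachability graph, sweep every distinct epsilon level
# descending, track components of the subgraph with edges strictly
# below epsilon, and extract clusters by excess of mass.
oracle_cluster_count <- function(xy, mcs = 5, ms = mcs) {
  n <- nrow(xy)
  if (n < mcs || ms > n) return(0L)
  d <- as.matrix(dist(xy))
  core <- vapply(seq_len(n), function(i) sort(d[i, ])[ms], numeric(1))
  mr <- pmax(d, outer(core, core, pmax)); diag(mr) <- 0
  eps_levels <- sort(unique(mr[upper.tri(mr)]), decreasing = TRUE)
  comps <- function(pts, eps) {
    adj <- mr[pts, pts, drop = FALSE] < eps
    seen <- rep(FALSE, length(pts)); out <- list()
    for (s in seq_along(pts)) {
      if (seen[s]) next
      q <- s; comp <- integer(0)
      while (length(q)) {
        u <- q[1]; q <- q[-1]
        if (seen[u]) next
        seen[u] <- TRUE; comp <- c(comp, u)
        q <- c(q, which(adj[u, ] & !seen))
      }
      out[[length(out) + 1]] <- pts[comp]
    }
    out
  }
  clusters <- list(list(points = seq_len(n), birth = 0))
  parent <- 0; stability <- 0; active <- 1L
  for (eps in eps_levels) {
    lam <- 1 / eps
    for (ci in active) {
      pts <- clusters[[ci]]$points
      cc <- comps(pts, eps)
      big <- Filter(function(x) length(x) >= mcs, cc)
      if (length(big) >= 2) {
        stability[ci] <- stability[ci] + (lam - clusters[[ci]]$birth) * length(pts)
        active <- setdiff(active, ci)
        for (bp in big) {
          clusters[[length(clusters) + 1]] <- list(points = bp, birth = lam)
          parent[length(clusters)] <- ci
          stability[length(clusters)] <- 0
          active <- c(active, length(clusters))
        }
      } else if (length(big) == 1) {
        leaving <- setdiff(pts, big[[1]])
        if (length(leaving)) {
          stability[ci] <- stability[ci] +
            (lam - clusters[[ci]]$birth) * length(leaving)
          clusters[[ci]]$points <- big[[1]]
        }
      } else {
        stability[ci] <- stability[ci] + (lam - clusters[[ci]]$birth) * length(pts)
        active <- setdiff(active, ci)
      }
    }
  }
  m <- length(clusters)
  kids <- lapply(seq_len(m), function(i) which(parent == i))
  sub <- numeric(m); sel <- logical(m)
  for (i in rev(seq_len(m))) {
    if (length(kids[[i]]) == 0) {
      sub[i] <- stability[i]; sel[i] <- TRUE
    } else {
      s <- sum(sub[kids[[i]]])
      if (stability[i] >= s) { sub[i] <- stability[i]; sel[i] <- TRUE }
      else sub[i] <- s
    }
  }
  cnt <- 0L
  for (i in seq_len(m)) {
    if (!sel[i]) next
    p <- parent[i]; shadow <- FALSE
    while (p > 0) { if (sel[p]) { shadow <- TRUE; break }; p <- parent[p] }
    if (!shadow) cnt <- cnt + 1L
  }
  cnt
}

# All-pairs frame-level matching oracle.
oracle_match_frame <- function(pred, events, tol) {
  nE <- nrow(events)
  ev_matched <- logical(nE)
  pr_matched <- logical(length(pred))
  if (nE > 0 && length(pred) > 0) {
    for (i in seq_len(nE)) {
      frames_i <- events$start_frame[i]:events$end_frame[i]
      for (j in seq_along(pred)) {
        if (any(abs(pred[j] - frames_i) <= tol)) {
          ev_matched[i] <- TRUE
          pr_matched[j] <- TRUE
        }
      }
    }
  }
  len <- if (nE) events$end_frame - events$start_frame + 1L else integer(0)
  list(tp = sum(len[ev_matched]), fp = sum(!pr_matched),
       fn = sum(len[!ev_matched]), ev_matched = ev_matched)
}

# Segment-level oracle: enumerate every segment and every event frame.
oracle_match_segment <- function(pred, ev_matched, events, total, tol, L) {
  fp <- 0L
  if (length(pred)) {
    for (sg in unique(pred %/% L)) {
      a <- sg * L; b <- min((sg + 1L) * L - 1L, total - 1L)
      touches <- FALSE
      if (nrow(events)) {
        for (i in seq_len(nrow(events))) {
          widened <- (events$start_frame[i] - tol):(events$end_frame[i] + tol)
          if (any(widened >= a & widened <= b)) { touches <- TRUE; break }
        }
      }
      if (!touches) fp <- fp + 1L
    }
  }
  list(tp = sum(ev_matched), fp = fp, fn = sum(!ev_matched))
}

# Random small evaluation instance generator.
random_eval_instance <- function() {
  total <- sample(100:1000, 1)
  n_ev <- sample(0:10, 1)
  events <- event_intervals()
  if (n_ev > 0) {
    starts <- sort(sample(0:(total - 2), n_ev))
    ends <- pmin(starts + sample(0:20, n_ev, replace = TRUE), total - 1L)
    # sequential non-overlap filter
    keep <- rep(TRUE, n_ev); last_end <- -1L
    for (i in seq_len(n_ev)) {
      if (starts[i] <= last_end) keep[i] <- FALSE else last_end <- ends[i]
    }
    events <- event_intervals(starts[keep], ends[keep])
  }
  n_pred <- sample(0:50, 1)
  pred <- sort(unique(sample(0:(total - 1), n_pred, replace = TRUE)))
  list(total = total, events = events, pred = pred)
}
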