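# Frame-to-frame trajectory linking with gap closing. Candidate links are
# limited to a maximum displacement; each frame's assignment is solved as an
# optimal bipartite matching (shortest augmenting path algorithm) so the
# result is deterministic and independent of input ordering.

#' Linking parameters
#'
#' Defaults follow the slow-movie tracking settings: maximum frame-to-frame
#' displacement of 5 pixels (725 nm at 145 nm/pixel), gap closing over up to
#' 3 missed frames (fluorophore blinking), and a minimum track length of 2
#' detections.
#'
#' @param max_disp maximum displacement between linked detections, um.
#' @param max_gap maximum number of consecutive missed frames bridged by gap
#'   closing.
#' @param min_len minimum number of detections per reported track.
#' @param pixel_size pixel size, um; kept for converting pixel-unit inputs.
#' @return An object of class `link_params`.
#' @export
link_params <- function(max_disp = 0.725, max_gap = 3, min_len = 2,
                        pixel_size = 0.145) {
  .check_number(max_disp, "max_disp", lower = 1e-12)
  .check_count(max_gap, "max_gap", lower = 0)
  .check_count(min_len, "min_len", lower = 1)
  .check_number(pixel_size, "pixel_size", lower = 1e-12)
  structure(list(max_disp = max_disp, max_gap = as.integer(max_gap),
                 min_len = as.integer(min_len), pixel_size = pixel_size),
            class = "link_params")
}

# Minimum-cost assignment for a square cost matrix (shortest augmenting
# path with dual potentials, O(n^3)). Returns, for each row, the assigned
# column. Entries >= .lap_big are treated as forbidden.
#' @keywords internal
.lap_big <- 1e12

#' @keywords internal
.solve_lap <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  u <- numeric(n + 1L)
  v <- numeric(n + 1L)
  p <- integer(n + 1L)          # p[j+1]: row matched to column j (0 = none)
  way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(Inf, n + 1L)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      delta <- Inf
      j1 <- 0L
      free_j <- which(!used[-1L])
      if (length(free_j)) {
        cur <- cost[i0, free_j] - u[i0 + 1L] - v[free_j + 1L]
        upd <- cur < minv[free_j + 1L]
        minv[free_j[upd] + 1L] <- cur[upd]
        way[free_j[upd] + 1L] <- j0
        k <- which.min(minv[free_j + 1L])
        delta <- minv[free_j[k] + 1L]
        j1 <- free_j[k]
      }
      if (!is.finite(delta)) stop("assignment infeasible", call. = FALSE)
      iu <- which(used)                       # used columns, as j + 1
      u[p[iu] + 1L] <- u[p[iu] + 1L] + delta  # dual potentials
      v[iu] <- v[iu] - delta
      minv[!used] <- minv[!used] - delta
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assign <- integer(n)
  for (j in seq_len(n)) if (p[j + 1L] > 0L) assign[p[j + 1L]] <- j
  assign
}

# Match na "old" items to nb "new" items given a cost matrix with NA for
# forbidden pairs. Unmatched items pay `b` each; any allowed link is cheaper
# than leaving both ends unmatched, so the matching has maximum cardinality
# and, among those, minimum total cost. Returns an integer vector over old
# items (index of matched new item, or NA).
#' @keywords internal
.match_bipartite <- function(cost, b) {
  na_ <- nrow(cost)
  nb_ <- ncol(cost)
  if (na_ == 0L || nb_ == 0L) return(rep(NA_integer_, na_))
  n <- na_ + nb_
  C <- matrix(0, n, n)
  C[seq_len(na_), seq_len(nb_)] <- ifelse(is.na(cost), .lap_big, cost)
  C[seq_len(na_), nb_ + seq_len(na_)] <- .lap_big
  C[cbind(seq_len(na_), nb_ + seq_len(na_))] <- b
  C[na_ + seq_len(nb_), seq_len(nb_)] <- .lap_big
  C[cbind(na_ + seq_len(nb_), seq_len(nb_))] <- b
  assign <- .solve_lap(C)
  out <- assign[seq_len(na_)]
  out[out > nb_] <- NA_integer_
  out
}

#' Link localizations into trajectories
#'
#' Assembles a localization table into tracks. For every frame, detections
#' are matched to open track ends (including ends up to `max_gap` frames in
#' the past, for blinking-tolerant gap closing) by an optimal bipartite
#' assignment that minimizes total squared displacement among candidate
#' pairs closer than `max_disp`; matching has maximum cardinality within
#' that radius. Unmatched detections open new tracks; track ends unmatched
#' for more than `max_gap` frames are closed. Tracks with fewer than
#' `min_len` detections are discarded.
#'
#' @param localizations data.frame with columns `frame` (integer), `x_um`,
#'   `y_um`. Additional columns are ignored.
#' @param params a [link_params()].
#' @return data.frame with columns `track_id`, `frame`, `x_um`, `y_um`,
#'   ordered by track and frame. Empty input yields an empty table.
#' @export
link_localizations <- function(localizations, params = link_params()) {
  stopifnot(inherits(params, "link_params"))
  empty <- data.frame(track_id = integer(), frame = integer(),
                      x_um = numeric(), y_um = numeric())
  if (is.null(localizations) || nrow(localizations) == 0L) return(empty)
  stopifnot(all(c("frame", "x_um", "y_um") %in% names(localizations)))
  locs <- localizations[order(localizations$frame, localizations$x_um,
                              localizations$y_um), , drop = FALSE]
  frames <- sort(unique(locs$frame))
  max_d2 <- params$max_disp^2
  b <- max_d2 + 1

  track_of_row <- integer(nrow(locs))
  # open track ends
  end_track <- integer(0)
  end_frame <- integer(0)
  end_x <- numeric(0)
  end_y <- numeric(0)
  next_track <- 1L

  row_by_frame <- split(seq_len(nrow(locs)), locs$frame)
  for (f in frames) {
    rows <- row_by_frame[[as.character(f)]]
    px <- locs$x_um[rows]
    py <- locs$y_um[rows]
    alive <- which(f - end_frame <= params$max_gap + 1L & end_frame < f)
    matched_new <- rep(NA_integer_, length(rows))
    if (length(alive)) {
      d2 <- outer(end_x[alive], px, "-")^2 + outer(end_y[alive], py, "-")^2
      d2[d2 > max_d2] <- NA_real_
      # assignment decomposes over connected components of the candidate
      # graph; singleton pairs (the common case at realistic densities)
      # need no solver
      m <- rep(NA_integer_, length(alive))
      edges <- which(!is.na(d2), arr.ind = TRUE)
      if (nrow(edges)) {
        comp_t <- seq_len(nrow(d2))          # union-find over track nodes
        comp_d <- rep(NA_integer_, ncol(d2)) # component of each detection
        find <- function(i) { while (comp_t[i] != i) i <- comp_t[i]; i }
        for (e in seq_len(nrow(edges))) {
          ti <- edges[e, 1L]; dj <- edges[e, 2L]
          if (is.na(comp_d[dj])) comp_d[dj] <- find(ti)
          else comp_t[find(ti)] <- find(comp_d[dj])
        }
        comp_of_t <- vapply(seq_len(nrow(d2)), find, integer(1))
        comp_d[!is.na(comp_d)] <-
          vapply(comp_d[!is.na(comp_d)], find, integer(1))
        for (cc in unique(comp_of_t[edges[, 1L]])) {
          ti <- which(comp_of_t == cc & rowSums(!is.na(d2)) > 0L)
          dj <- which(comp_d == cc)
          if (length(ti) == 1L && length(dj) == 1L) {
            m[ti] <- dj
          } else {
            sub <- .match_bipartite(d2[ti, dj, drop = FALSE], b)
            m[ti] <- dj[sub]
          }
        }
      }
      for (k in which(!is.na(m))) {
        j <- m[k]
        a <- alive[k]
        track_of_row[rows[j]] <- end_track[a]
        end_frame[a] <- f
        end_x[a] <- px[j]
        end_y[a] <- py[j]
        matched_new[j] <- a
      }
    }
    # unmatched detections start new tracks
    for (j in which(is.na(matched_new))) {
      track_of_row[rows[j]] <- next_track
      end_track <- c(end_track, next_track)
      end_frame <- c(end_frame, f)
      end_x <- c(end_x, px[j])
      end_y <- c(end_y, py[j])
      next_track <- next_track + 1L
    }
    # close stale ends
    keep <- f - end_frame <= params$max_gap
    end_track <- end_track[keep]
    end_frame <- end_frame[keep]
    end_x <- end_x[keep]
    end_y <- end_y[keep]
  }

  out <- data.frame(track_id = track_of_row, frame = locs$frame,
                    x_um = locs$x_um, y_um = locs$y_um)
  len <- table(out$track_id)
  keep_ids <- as.integer(names(len)[len >= params$min_len])
  out <- out[out$track_id %in% keep_ids, , drop = FALSE]
  if (nrow(out)) {
    out <- out[order(out$track_id, out$frame), , drop = FALSE]
    out$track_id <- match(out$track_id, unique(out$track_id))
  }
  rownames(out) <- NULL
  out
}
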