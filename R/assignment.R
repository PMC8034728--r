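# Linear assignment by the Jonker-Volgenant / shortest-augmenting-path
# algorithm with dual potentials (O(n^3)). Solves the square min-cost perfect
# matching used for frame-to-frame track linking; forbidden pairs carry a
# large finite cost so a perfect matching always exists.

#' Solve a square linear assignment problem
#'
#' @param cost Square numeric cost matrix; `Inf` marks forbidden pairs.
#' @return List with `match` (for each row, the assigned column) and `cost`
#'   (total cost of the optimal assignment).
#' @examples
#' solve_assignment(matrix(c(4, 2, 1, 3), 2, 2))
#' @export
solve_assignment <- function(cost) {
  if (!is.matrix(cost) || nrow(cost) != ncol(cost))
    abort("`cost` must be a square matrix.", class = "apoptomap_config_error")
  n <- nrow(cost)
  if (n == 0L) return(list(match = integer(), cost = 0))
  big <- {
    f <- cost[is.finite(cost)]
    (if (length(f) > 0L) max(abs(f), 1) else 1) * n * 8 + 1
  }
  C <- cost
  C[!is.finite(C)] <- big

  u <- numeric(n)                # row potentials
  v <- numeric(n + 1L)           # column potentials; index 1 is virtual col 0
  p <- integer(n + 1L)           # p[j+1]: row matched to column j (0 = free)
  way <- integer(n + 1L)         # predecessor column on the alternating path

  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(Inf, n)
    used <- logical(n + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      free <- which(!used[-1L])                 # unvisited real columns
      cur <- C[i0, free] - u[i0] - v[free + 1L]
      upd <- cur < minv[free]
      minv[free[upd]] <- cur[upd]
      way[free[upd] + 1L] <- j0
      j1 <- free[which.min(minv[free])]
      delta <- minv[j1]
      # dual update over visited columns, slack update over the rest
      vis <- which(used)                        # 1-based: includes virtual col
      u[p[vis]] <- u[p[vis]] + delta
      v[vis] <- v[vis] - delta
      minv[free] <- minv[free] - delta
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {                                    # augment
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  match <- integer(n)
  match[p[-1L]] <- seq_len(n)
  list(match = match, cost = sum(C[cbind(seq_len(n), match)]))
}
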