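# Sparse 8-connected component labeling on a logical image.
#
# Works on the indices of active pixels only (detection footprints are
# sparse), using union-find with path halving. Returns a list of integer
# vectors of linear (column-major) pixel indices, one per component, in
# increasing order of their smallest member.
label_components_8 <- function(active) {
  h <- nrow(active); w <- ncol(active)
  idx <- which(active)
  n <- length(idx)
  if (n == 0L) return(list())
  if (n == 1L) return(list(idx))

  # rank lookup: pos[linear index] = position in idx (0 when inactive)
  pos <- integer(h * w)
  pos[idx] <- seq_len(n)
  row <- ((idx - 1L) %% h) + 1L

  edges_a <- integer(0); edges_b <- integer(0)
  add_edges <- function(off, ok) {
    cand <- idx + off
    keep <- ok & cand >= 1L & cand <= h * w
    keep[keep] <- pos[cand[keep]] > 0L
    list(a = pos[idx[keep]], b = pos[cand[keep]])
  }
  # four forward neighbor offsets cover all 8-neighbor pairs once
  south <- add_edges(1L, row < h)
  east <- add_edges(h, rep(TRUE, n))
  se <- add_edges(h + 1L, row < h)
  ne <- add_edges(h - 1L, row > 1L)
  ea <- c(south$a, east$a, se$a, ne$a)
  eb <- c(south$b, east$b, se$b, ne$b)

  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (k in seq_along(ea)) {
    ra <- find(ea[k]); rb <- find(eb[k])
    if (ra != rb) parent[rb] <- ra
  }
  root <- vapply(seq_len(n), find, integer(1))
  comps <- split(idx, root)
  comps <- comps[order(vapply(comps, min, numeric(1)))]
  names(comps) <- NULL
  comps
}

# Largest 8-connected component of a logical image (ties broken by smallest
# pixel index); returns a logical matrix.
largest_component_8 <- function(active) {
  comps <- label_components_8(active)
  out <- matrix(FALSE, nrow(active), ncol(active))
  if (length(comps) == 0L) return(out)
  sizes <- lengths(comps)
  out[comps[[which.max(sizes)]]] <- TRUE
  out
}
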