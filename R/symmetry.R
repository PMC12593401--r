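# Space-group machinery: xyz-notation operator parsing, a whitelist of
# supported groups (general positions only), and symmetry detection against
# that whitelist.

#' Parse a symmetry operator in xyz notation
#'
#' @param s Operator string such as `"-x, y+1/2, -z+1/2"`.
#' @return List with 3x3 integer rotation part `W` and translation `w`
#'   (fractional), acting on column vectors: `x' = W x + w`.
#' @export
parse_symop <- function(s) {
  s <- gsub("\\s", "", tolower(s))
  parts <- strsplit(s, ",")[[1]]
  if (length(parts) != 3) stop("bad symmetry operator: ", s)
  if (grepl("[^-xyz0-9+/.]", paste(parts, collapse = ""))) {
    stop("bad symmetry operator: ", s)
  }
  evalpart <- function(p, x, y, z) {
    eval(parse(text = p), list(x = x, y = y, z = z))
  }
  w <- vapply(parts, evalpart, 0, x = 0, y = 0, z = 0)
  W <- matrix(0, 3, 3)
  for (k in 1:3) {
    e <- c(0, 0, 0); e[k] <- 1
    W[, k] <- vapply(parts, evalpart, 0, x = e[1], y = e[2], z = e[3]) - w
  }
  list(W = W, w = as.numeric(w) %% 1)
}

# general-position operators for the supported groups
.sg_xyz <- list(
  "P1"      = list(number = 1L,  system = "triclinic",
                   ops = c("x,y,z")),
  "P-1"     = list(number = 2L,  system = "triclinic",
                   ops = c("x,y,z", "-x,-y,-z")),
  "P21"     = list(number = 4L,  system = "monoclinic",
                   ops = c("x,y,z", "-x,y+1/2,-z")),
  "P21/c"   = list(number = 14L, system = "monoclinic",
                   ops = c("x,y,z", "-x,y+1/2,-z+1/2", "-x,-y,-z",
                           "x,-y+1/2,z+1/2")),
  "C2/c"    = list(number = 15L, system = "monoclinic",
                   ops = c("x,y,z", "-x,y,-z+1/2", "-x,-y,-z", "x,-y,z+1/2",
                           "x+1/2,y+1/2,z", "-x+1/2,y+1/2,-z+1/2",
                           "-x+1/2,-y+1/2,-z", "x+1/2,-y+1/2,z+1/2")),
  "P212121" = list(number = 19L, system = "orthorhombic",
                   ops = c("x,y,z", "-x+1/2,-y,z+1/2", "-x,y+1/2,-z+1/2",
                           "x+1/2,-y+1/2,-z")),
  "Pna21"   = list(number = 33L, system = "orthorhombic",
                   ops = c("x,y,z", "-x,-y,z+1/2", "x+1/2,-y+1/2,z",
                           "-x+1/2,y+1/2,z+1/2")),
  "Pbca"    = list(number = 61L, system = "orthorhombic",
                   ops = c("x,y,z", "-x+1/2,-y,z+1/2", "-x,y+1/2,-z+1/2",
                           "x+1/2,-y+1/2,-z", "-x,-y,-z", "x+1/2,y,-z+1/2",
                           "x,-y+1/2,z+1/2", "-x+1/2,y+1/2,z"))
)

# 48 cubic point-group operations (signed permutation matrices)
.cubic_point_ops <- local({
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  out <- list()
  for (p in perms) for (s1 in c(-1, 1)) for (s2 in c(-1, 1)) for (s3 in c(-1, 1)) {
    W <- matrix(0, 3, 3)
    sg <- c(s1, s2, s3)
    for (k in 1:3) W[k, p[k]] <- sg[k]
    out[[length(out) + 1]] <- W
  }
  out
})

#' Supported space groups
#' @return Character vector of Hermann-Mauguin style names accepted by the
#'   generator (general positions only).
#' @export
supported_space_groups <- function() names(.sg_xyz)

#' Operators of a supported space group
#'
#' @param sg Space group name (e.g. `"P21/c"`) or number from the supported
#'   whitelist; additionally `"Fm-3m"` / 225 (full cubic operator set with
#'   face centering) is available for symmetry detection.
#' @return List of `list(W, w)` operators.
#' @export
space_group_ops <- function(sg) {
  if (identical(sg, "Fm-3m") || identical(sg, 225) || identical(sg, 225L)) {
    cent <- list(c(0, 0, 0), c(0, .5, .5), c(.5, 0, .5), c(.5, .5, 0))
    out <- list()
    for (W in .cubic_point_ops) for (tc in cent) {
      out[[length(out) + 1]] <- list(W = W, w = tc)
    }
    return(out)
  }
  key <- if (is.numeric(sg)) {
    nm <- names(.sg_xyz)[vapply(.sg_xyz, function(g) g$number == sg, TRUE)]
    if (length(nm) == 0) stop("unsupported space group number ", sg)
    nm
  } else {
    if (!sg %in% names(.sg_xyz)) stop("unsupported space group ", sg)
    sg
  }
  lapply(.sg_xyz[[key]]$ops, parse_symop)
}

sg_number <- function(name) {
  if (identical(name, "Fm-3m")) return(225L)
  .sg_xyz[[name]]$number
}
sg_system <- function(name) .sg_xyz[[name]]$system

# does operator (W, w + shift) map the site set onto itself within symprec?
# nearest-image fractional differences suffice at symprec scale.
op_maps_structure <- function(crystal, W, w, symprec) {
  fr <- crystal$frac_coords
  cell <- as.matrix(crystal$lattice)
  n <- nrow(fr)
  mapped <- t(W %*% t(fr) + w)
  perm <- integer(n)
  for (i in seq_len(n)) {
    d <- fr - matrix(mapped[i, ], n, 3, byrow = TRUE)
    d <- d - round(d)
    ds <- sqrt(rowSums((d %*% cell)^2))
    ds[crystal$species != crystal$species[i]] <- Inf
    j <- which.min(ds)
    if (ds[j] > symprec) return(NULL)
    perm[i] <- j
  }
  if (anyDuplicated(perm)) return(NULL)
  perm
}

#' Detect and enforce whitelist space-group symmetry
#'
#' Tests each supported space group's operator set (plus the full cubic
#' `Fm-3m` set) for invariance of the site list at tolerance `symprec`,
#' searching candidate origin shifts, and returns the richest group found.
#' Matched structures are symmetrized by averaging each orbit so the result
#' obeys the group exactly; the procedure is idempotent and falls back to P1.
#'
#' @param crystal A `csp_crystal`.
#' @param symprec Cartesian distance tolerance in Angstrom (default 0.2).
#' @return List with `space_group` (int), `name`, and `structure` (the
#'   symmetrized `csp_crystal`, sites within `symprec` of the input).
#' @export
symmetrize <- function(crystal, symprec = 0.2) {
  out <- symmetrize_once(crystal, symprec)
  # iterate the orbit averaging to its fixed point so the operation is
  # strictly idempotent even when the detected origin is inexact
  for (it in 1:6) {
    nxt <- symmetrize_once(out$structure, symprec)
    d <- nxt$structure$frac_coords - out$structure$frac_coords
    d <- abs(d - round(d))
    out <- nxt
    if (max(d) < 1e-12) break
  }
  out
}

symmetrize_once <- function(crystal, symprec = 0.2) {
  cands <- c(list(list(name = "Fm-3m", nops = 192L)),
             lapply(names(.sg_xyz), function(nm) {
               list(name = nm, nops = length(.sg_xyz[[nm]]$ops))
             }))
  ord <- order(vapply(cands, function(x) x$nops, 0), decreasing = TRUE)
  fr <- crystal$frac_coords
  for (k in ord) {
    nm <- cands[[k]]$name
    if (nm == "P1") next
    ops <- space_group_ops(nm)
    # candidate origin shifts: 0 and displacements solving W p + w + t = p
    shifts <- list(c(0, 0, 0))
    nontriv <- Filter(function(o) !all(o$W == diag(3)) || any(o$w %% 1 != 0), ops)
    if (length(nontriv) > 0 && nrow(fr) <= 64) {
      o1 <- nontriv[[1]]
      for (i in seq_len(nrow(fr))) for (j in seq_len(nrow(fr))) {
        if (crystal$species[i] != crystal$species[j]) next
        # want W x_i + w + (I - W) t = x_j  (mod 1) for origin t
        M <- diag(3) - o1$W
        rhs <- fr[j, ] - (o1$W %*% fr[i, ] + o1$w)
        t0 <- tryCatch(solve(M, rhs), error = function(e) NULL)
        if (!is.null(t0) && all(is.finite(t0))) {
          shifts[[length(shifts) + 1]] <- as.numeric(t0) %% 1
        }
      }
      shifts <- unique(lapply(shifts, function(s) round(s, 10)))
      if (length(shifts) > 40) shifts <- shifts[1:40]
    }
    for (t0 in shifts) {
      perms <- list(); ok <- TRUE
      for (op in ops) {
        w_sh <- op$w + (diag(3) - op$W) %*% t0
        perm <- op_maps_structure(crystal, op$W, as.numeric(w_sh), symprec)
        if (is.null(perm)) { ok <- FALSE; break }
        perms[[length(perms) + 1]] <- list(op = op, w = as.numeric(w_sh),
                                           perm = perm)
      }
      if (!ok) next
      # orbit-average: replace each site by the mean of its images pulled back
      newfr <- fr * 0
      for (i in seq_len(nrow(fr))) {
        acc <- matrix(0, length(perms), 3)
        for (q in seq_along(perms)) {
          pq <- perms[[q]]
          img <- pq$op$W %*% fr[i, ] + pq$w    # image of i = site perm[i]
          j <- pq$perm[i]
          # pull image back into i's frame not needed; average forward images
          d <- img - fr[j, ]
          acc[q, ] <- as.numeric(img - round(d))   # same branch as x_j
        }
        # distribute the averaged orbit positions
        for (q in seq_along(perms)) {
          pq <- perms[[q]]
          newfr[pq$perm[i], ] <- newfr[pq$perm[i], ] + acc[q, ] / length(perms)
        }
      }
      # averaging forward images accumulates each target exactly once per op
      out <- crystal
      out$frac_coords <- newfr %% 1
      out$space_group <- sg_number(nm)
      return(list(space_group = sg_number(nm), name = nm, structure = out))
    }
  }
  out <- crystal
  out$space_group <- 1L
  list(space_group = 1L, name = "P1", structure = out)
}
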