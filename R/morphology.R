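# Simplified TRN morphologies: a soma cylinder plus a basal dendrite tree of
# constant-diameter cylindrical sections. Only topology, lengths and diameters
# enter the cable model; 3D coordinates exist solely for SWC round-trips.

#' Construct a morphology from a section table
#'
#' A morphology is a tibble of sections with class `trn_morphology`. Each
#' section is a cylinder of constant diameter. Surface areas are lateral only
#' (no end caps), the convention of compartmental simulators.
#'
#' @param sections tibble with columns `id` (integer), `parent_id` (integer,
#'   `NA` for the root), `kind` (`"soma"` or `"basal"`), `length` (um),
#'   `diam` (um) and optionally `n_comp` (compartments per section; default
#'   one per 20 um).
#' @param label optional text label.
#' @param max_comp_length target compartment length (um) used when `n_comp`
#'   is absent.
#' @return a `trn_morphology` tibble.
#' @export
morphology <- function(sections, label = "morphology", max_comp_length = 20) {
  sections <- tibble::as_tibble(sections)
  required <- c("id", "parent_id", "kind", "length", "diam")
  if (!all(required %in% names(sections))) {
    stop_invalid(paste("sections must have columns:", paste(required, collapse = ", ")))
  }
  if (any(sections$length <= 0) || any(sections$diam <= 0)) {
    stop_invalid("section lengths and diameters must be positive")
  }
  if (anyDuplicated(sections$id)) stop_invalid("duplicate section ids")
  roots <- which(is.na(sections$parent_id))
  if (length(roots) != 1 || sections$kind[roots] != "soma") {
    stop_invalid("morphology must have exactly one root section of kind 'soma'")
  }
  if (!all(stats::na.omit(sections$parent_id) %in% sections$id)) {
    stop_invalid("parent_id refers to a missing section")
  }
  # cycle check: walk to root from every section
  idx <- match(sections$parent_id, sections$id)
  for (i in seq_len(nrow(sections))) {
    seen <- logical(nrow(sections))
    j <- i
    while (!is.na(idx[j])) {
      if (seen[j]) stop_invalid("section parents form a cycle")
      seen[j] <- TRUE
      j <- idx[j]
    }
  }
  if (!("n_comp" %in% names(sections))) {
    sections$n_comp <- pmax(1L, as.integer(ceiling(sections$length / max_comp_length)))
  }
  sections <- order_sections(sections)
  structure(sections,
            class = c("trn_morphology", class(tibble::tibble())),
            label = label)
}

# reorder so every parent precedes its children
order_sections <- function(sections) {
  n <- nrow(sections)
  placed <- logical(n)
  ord <- integer(0)
  repeat {
    ready <- which(!placed &
                     (is.na(sections$parent_id) |
                        sections$parent_id %in% sections$id[placed]))
    if (length(ready) == 0) break
    ord <- c(ord, ready)
    placed[ready] <- TRUE
  }
  sections[ord, ]
}

#' Soma cylinder matched to a surface area
#'
#' Builds the single-cylinder soma section. Its lateral surface area is
#' `2 * pi * radius * length`; end caps are excluded.
#'
#' @param radius soma radius (um).
#' @param length soma length (um).
#' @return a one-row section tibble of kind `"soma"`.
#' @export
soma_cylinder <- function(radius, length) {
  if (!is.numeric(radius) || !is.numeric(length) || radius <= 0 || length <= 0) {
    stop_invalid("soma radius and length must be positive")
  }
  tibble::tibble(id = 1L, parent_id = NA_integer_, kind = "soma",
                 length = length, diam = 2 * radius, n_comp = 1L)
}

#' Lateral surface area of sections and morphologies
#'
#' @param x a morphology or section tibble.
#' @return total lateral area (um^2), `pi * diam * length` summed over sections.
#' @export
surface_area <- function(x) sum(pi * x$diam * x$length)

#' Surface area of the basal dendrites only
#' @param m a `trn_morphology`.
#' @return area in um^2.
#' @export
dendritic_area <- function(m) {
  b <- m[m$kind == "basal", ]
  if (nrow(b) == 0) return(0)
  surface_area(b)
}

#' Path distance from the soma
#'
#' Distance along the tree from the soma (the origin: any point on the soma is
#' at distance 0) to the point at fraction `x` of a section.
#'
#' @param m a `trn_morphology`.
#' @param section_id section id.
#' @param x position along the section in `[0, 1]` (default: distal end).
#' @return distance in um.
#' @export
path_distance <- function(m, section_id, x = 1) {
  i <- match(section_id, m$id)
  if (is.na(i)) stop_not_found(paste("no section with id", section_id))
  if (m$kind[i] == "soma") return(0)
  d <- x * m$length[i]
  p <- m$parent_id[i]
  while (!is.na(p)) {
    j <- match(p, m$id)
    if (m$kind[j] == "soma") break
    d <- d + m$length[j]
    p <- m$parent_id[j]
  }
  d
}

# path distance of each section's midpoint, vectorized (used for the IT gradient)
section_midpoint_distances <- function(m) {
  vapply(m$id, function(id) path_distance(m, id, 0.5), numeric(1))
}

#' Surface-area profile against path distance
#'
#' Bins the membrane area of the basal tree by path distance from the soma.
#'
#' @param m a `trn_morphology`.
#' @param bin bin width in um (default 20).
#' @return tibble with `distance` (bin midpoint) and `area` (um^2 in the bin).
#' @export
area_profile <- function(m, bin = 20) {
  basal <- m[m$kind == "basal", ]
  if (nrow(basal) == 0) {
    return(tibble::tibble(distance = numeric(0), area = numeric(0)))
  }
  pieces <- purrr::map_dfr(seq_len(nrow(basal)), function(i) {
    id <- basal$id[i]
    d0 <- path_distance(m, id, 0)
    len <- basal$length[i]
    # split into 1-um slices for binning accuracy
    ns <- max(1L, ceiling(len))
    edges <- seq(0, len, length.out = ns + 1)
    mid <- d0 + (edges[-1] + edges[-(ns + 1)]) / 2
    tibble::tibble(distance = mid,
                   area = pi * basal$diam[i] * diff(edges))
  })
  pieces$bin <- floor(pieces$distance / bin)
  out <- dplyr::summarise(dplyr::group_by(pieces, .data$bin),
                          area = sum(.data$area), .groups = "drop")
  tibble::tibble(distance = (out$bin + 0.5) * bin, area = out$area)
}

#' Synthetic basal dendrite tree
#'
#' Generates a parametric soma-plus-basal morphology: `n_stems` stems, each a
#' balanced binary tree with `branch_orders` bifurcations, section diameters
#' taken from `taper_profile` evaluated at the section midpoint path distance.
#' Section lengths are jittered (deterministically per `rng_seed`) and
#' renormalized so the summed dendritic length equals `total_length` exactly.
#'
#' @param n_stems number of stems leaving the soma (>= 1).
#' @param total_length total basal dendritic length (um).
#' @param taper_profile function mapping path distance (um) to diameter (um).
#' @param branch_orders number of bifurcation levels per stem (0 = unbranched).
#' @param rng_seed integer seed; the same seed yields an identical morphology.
#' @param soma_radius,soma_length soma cylinder dimensions (um).
#' @param label text label.
#' @return a `trn_morphology`.
#' @export
synth_basal_tree <- function(n_stems = 4, total_length = 1200,
                             taper_profile = function(d) 1.2 * exp(-d / 400) + 0.3,
                             branch_orders = 2, rng_seed = 1,
                             soma_radius = 7, soma_length = 14,
                             label = "synthetic") {
  if (n_stems < 1) stop_invalid("n_stems must be >= 1")
  if (total_length <= 0) stop_invalid("total_length must be positive")
  per_stem <- 2^(branch_orders + 1) - 1
  n_sec <- n_stems * per_stem
  lens <- local_seed(rng_seed, {
    l <- runif(n_sec, 0.9, 1.1)
    l / sum(l) * total_length
  })
  soma <- soma_cylinder(soma_radius, soma_length)
  rows <- list(soma)
  next_id <- 2L
  k <- 0L
  add_subtree <- function(parent_id, parent_dist, depth) {
    k <<- k + 1L
    len <- lens[k]
    mid <- parent_dist + len / 2
    diam <- taper_profile(mid)
    if (any(!is.finite(diam)) || any(diam <= 0)) {
      stop_invalid("taper_profile must be positive over the tree extent")
    }
    id <- next_id
    next_id <<- next_id + 1L
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      id = id, parent_id = parent_id, kind = "basal",
      length = len, diam = diam,
      n_comp = pmax(1L, as.integer(ceiling(len / 20))))
    if (depth < branch_orders) {
      add_subtree(id, parent_dist + len, depth + 1L)
      add_subtree(id, parent_dist + len, depth + 1L)
    }
  }
  for (s in seq_len(n_stems)) add_subtree(1L, 0, 0L)
  morphology(dplyr::bind_rows(rows), label = label)
}

# deterministic 3D layout for SWC export: unit directions from a golden-angle
# spiral indexed by section order
section_direction <- function(i) {
  phi <- 2.399963229728653  # golden angle
  theta <- phi * i
  z <- 1 - 2 * ((i * 0.6180339887498949) %% 1)
  r <- sqrt(max(0, 1 - z^2))
  c(r * cos(theta), r * sin(theta), z)
}

#' Write a morphology to SWC
#'
#' The soma cylinder becomes a two-point type-1 chain along x; every basal
#' section becomes a single SWC point at its distal end (radius `diam / 2`),
#' parented on its parent section's point. Coordinates are a deterministic
#' synthetic layout; only lengths, radii, and topology are meaningful.
#'
#' @param m a `trn_morphology`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_swc <- function(m, path) {
  soma_i <- which(m$kind == "soma")
  soma <- m[soma_i, ]
  pts <- list()
  # two-point soma chain along +x
  pts[[1]] <- c(1, 1, 0, 0, 0, soma$diam / 2, -1)
  pts[[2]] <- c(2, 1, soma$length, 0, 0, soma$diam / 2, 1)
  pt_of_section <- setNames(rep(NA_integer_, nrow(m)), m$id)
  pt_of_section[as.character(soma$id)] <- 1L  # basal sections attach at soma origin
  end_of_section <- list()
  end_of_section[[as.character(soma$id)]] <- c(0, 0, 0)
  next_pt <- 3L
  basal <- m[m$kind == "basal", ]
  for (i in seq_len(nrow(basal))) {
    sec <- basal[i, ]
    pstart <- end_of_section[[as.character(sec$parent_id)]]
    dirv <- section_direction(next_pt)
    pos <- pstart + dirv * sec$length
    pts[[next_pt]] <- c(next_pt, 3, pos[1], pos[2], pos[3], sec$diam / 2,
                        pt_of_section[[as.character(sec$parent_id)]])
    pt_of_section[[as.character(sec$id)]] <- next_pt
    end_of_section[[as.character(sec$id)]] <- pos
    next_pt <- next_pt + 1L
  }
  mat <- do.call(rbind, pts)
  lines <- apply(mat, 1, function(r) {
    sprintf("%d %d %.9f %.9f %.9f %.9f %d", as.integer(r[1]), as.integer(r[2]),
            r[3], r[4], r[5], r[6], as.integer(r[7]))
  })
  writeLines(c("# SWC export", lines), path)
  invisible(path)
}

#' Read an SWC morphology
#'
#' Parses the 7-column SWC standard (`#` comments allowed). Type-1 points form
#' the soma: a single point is read as a sphere-equivalent cylinder
#' (`length = diam = 2 * radius`, lateral area `4 * pi * r^2`), a chain as a
#' cylinder of the chain length and mean radius. Unbranched runs of basal
#' points with equal radius merge into one section, so a 3-point straight
#' neurite of constant radius reads as a single section.
#'
#' @param path SWC file path.
#' @param label text label for the morphology.
#' @return a `trn_morphology`.
#' @export
read_swc <- function(path, label = basename(path)) {
  raw <- readLines(path)
  raw <- trimws(sub("#.*$", "", raw))
  raw <- raw[nzchar(raw)]
  if (length(raw) == 0) stop_format("empty SWC file")
  fields <- strsplit(raw, "\\s+")
  if (any(lengths(fields) != 7)) stop_format("SWC rows must have 7 columns")
  mat <- do.call(rbind, lapply(fields, as.numeric))
  if (anyNA(mat)) stop_format("non-numeric SWC fields")
  id <- as.integer(mat[, 1]); type <- as.integer(mat[, 2])
  xyz <- mat[, 3:5, drop = FALSE]; radius <- mat[, 6]
  parent <- as.integer(mat[, 7])
  if (anyDuplicated(id)) stop_format("duplicate SWC sample ids")
  roots <- which(parent == -1)
  if (length(roots) == 0) stop_format("SWC file has no root sample")
  if (length(roots) > 1) stop_format("SWC file has more than one root sample")
  pidx <- match(parent, id)
  if (any(is.na(pidx) & parent != -1)) stop_format("SWC parent id not found")
  # cycle detection
  for (i in seq_along(id)) {
    seen <- logical(length(id)); j <- i
    while (parent[j] != -1) {
      if (seen[j]) stop_format("cyclic SWC parents")
      seen[j] <- TRUE
      j <- pidx[j]
    }
  }
  if (type[roots] != 1) stop_format("SWC root must be a soma (type 1) sample")

  soma_pts <- which(type == 1)
  if (length(soma_pts) == 1) {
    r <- radius[soma_pts]
    soma_len <- 2 * r; soma_diam <- 2 * r
  } else {
    seg_len <- vapply(soma_pts, function(i) {
      if (parent[i] == -1) return(0)
      sqrt(sum((xyz[i, ] - xyz[pidx[i], ])^2))
    }, numeric(1))
    soma_len <- sum(seg_len)
    if (soma_len <= 0) stop_format("degenerate soma chain in SWC")
    soma_diam <- 2 * mean(radius[soma_pts])
  }
  secs <- list(tibble::tibble(id = 1L, parent_id = NA_integer_, kind = "soma",
                              length = soma_len, diam = soma_diam))
  children <- split(seq_along(id), factor(parent, levels = id))
  n_children <- function(i) length(children[[as.character(id[i])]] %||% integer(0))
  sec_id <- 2L
  # walk from each basal point attached to the soma or a branch point
  emit <- function(start_i, parent_sec) {
    # follow an unbranched equal-radius run
    run <- start_i
    len <- sqrt(sum((xyz[start_i, ] - xyz[pidx[start_i], ])^2))
    cur <- start_i
    repeat {
      kids <- children[[as.character(id[cur])]] %||% integer(0)
      kids <- kids[type[kids] != 1]
      if (length(kids) == 1 && abs(radius[kids] - radius[start_i]) < 1e-9) {
        len <- len + sqrt(sum((xyz[kids, ] - xyz[cur, ])^2))
        cur <- kids
      } else break
    }
    if (len <= 0) stop_format("zero-length SWC segment")
    this_id <- sec_id
    sec_id <<- sec_id + 1L
    secs[[length(secs) + 1L]] <<- tibble::tibble(
      id = this_id, parent_id = parent_sec, kind = "basal",
      length = len, diam = 2 * radius[start_i])
    kids <- children[[as.character(id[cur])]] %||% integer(0)
    kids <- kids[type[kids] != 1]
    for (k in kids) emit(k, this_id)
  }
  for (i in soma_pts) {
    kids <- children[[as.character(id[i])]] %||% integer(0)
    kids <- kids[type[kids] != 1]
    for (k in kids) emit(k, 1L)
  }
  morphology(dplyr::bind_rows(secs), label = label)
}

#' @export
print.trn_morphology <- function(x, ...) {
  cat(sprintf("<trn_morphology '%s': %d sections, soma %.1f um^2, basal %.1f um^2>\n",
              attr(x, "label"), nrow(x),
              surface_area(x[x$kind == "soma", ]), dendritic_area(x)))
  NextMethod()
}
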