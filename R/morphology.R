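#' @useDynLib ihcable, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats approx median setNames runif
#' @importFrom utils head tail write.csv
NULL

REGIONS <- c("soma", "axon", "basal", "apical")

#' Branched neuron morphology as a section tree
#'
#' A `section_tree` is a table of unbranched neurite sections attached to a
#' single somatic root.  Each section carries its parent id, the arc-length
#' fraction along the parent at which it attaches, a region label, a length
#' and proximal/distal diameters (a tapering truncated cone).  The soma is a
#' special root section treated as one iso-potential sphere; path distances
#' are measured along the neurite path from the soma *center*, which is
#' distance 0.
#'
#' @param sections data.frame with columns `id`, `parent` (`NA` for the soma
#'   root), `parent_frac` (attachment fraction in `[0,1]`), `region` (one of
#'   `"soma"`, `"axon"`, `"basal"`, `"apical"`), `length` (um), `diam_p`,
#'   `diam_d` (um).  Optional columns `x`, `y`, `z` give the 3D position of
#'   the distal end of the section.
#' @return object of class `section_tree` (a validated data.frame with a
#'   `dist0` column: path distance of the proximal end of each section).
#' @export
section_tree <- function(sections) {
  need <- c("id", "parent", "parent_frac", "region", "length", "diam_p", "diam_d")
  miss <- setdiff(need, names(sections))
  if (length(miss) > 0)
    stop("section table is missing columns: ", paste(miss, collapse = ", "))
  sections <- as.data.frame(sections, stringsAsFactors = FALSE)
  if (!all(sections$region %in% REGIONS))
    stop("unknown region label(s): ",
         paste(setdiff(unique(sections$region), REGIONS), collapse = ", "))
  root <- which(is.na(sections$parent))
  if (length(root) != 1L)
    stop("section tree must have exactly one root (the soma), found ",
         length(root))
  if (sections$region[root] != "soma")
    stop("root section must be the soma")
  if (any(sections$length <= 0))
    stop("all section lengths must be > 0")
  if (any(sections$diam_p <= 0) || any(sections$diam_d <= 0))
    stop("all section diameters must be > 0")
  if (anyDuplicated(sections$id))
    stop("duplicate section ids")
  if (any(sections$parent_frac < 0 | sections$parent_frac > 1, na.rm = TRUE))
    stop("parent_frac must lie in [0,1]")
  idx <- match(sections$parent, sections$id)
  orphan <- which(!is.na(sections$parent) & is.na(idx))
  if (length(orphan) > 0)
    stop("structural error: section ", sections$id[orphan[1]],
         " references missing parent ", sections$parent[orphan[1]])
  ## cycle check + proximal path distance by traversal from the root
  n <- nrow(sections)
  dist0 <- rep(NA_real_, n)
  dist0[root] <- 0
  remaining <- setdiff(seq_len(n), root)
  repeat {
    ready <- remaining[!is.na(dist0[idx[remaining]])]
    if (length(ready) == 0) break
    p <- idx[ready]
    at_soma <- sections$region[p] == "soma"
    ## children of the soma attach at the soma center (distance 0)
    dist0[ready] <- ifelse(at_soma, 0,
                           dist0[p] + sections$parent_frac[ready] * sections$length[p])
    remaining <- setdiff(remaining, ready)
  }
  if (length(remaining) > 0)
    stop("structural error: cycle or disconnected section, e.g. id ",
         sections$id[remaining[1]])
  sections$dist0 <- dist0
  class(sections) <- c("section_tree", "data.frame")
  sections
}

#' @export
print.section_tree <- function(x, ...) {
  cat("<section_tree> ", nrow(x), " sections\n", sep = "")
  for (r in REGIONS) {
    sel <- x$region == r
    if (any(sel))
      cat(sprintf("  %-6s %3d sections, total length %.1f um\n",
                  r, sum(sel), sum(x$length[sel & r != "soma"])))
  }
  invisible(x)
}

#' Morphology summary
#'
#' Section counts and total lengths per region, suitable for JSON export.
#' @param tree a `section_tree`
#' @return named list
#' @export
morphology_summary <- function(tree) {
  stopifnot(inherits(tree, "section_tree"))
  per <- lapply(REGIONS, function(r) {
    sel <- tree$region == r
    list(n_sections = sum(sel),
         total_length_um = if (r == "soma") 0 else sum(tree$length[sel]),
         max_path_distance_um = if (any(sel))
           max(tree$dist0[sel] + tree$length[sel] * (r != "soma")) else 0)
  })
  names(per) <- REGIONS
  list(n_sections = nrow(tree), regions = per)
}

## SWC type codes: 1 soma, 2 axon, 3 basal dendrite, 4 apical dendrite
.swc_region <- c("1" = "soma", "2" = "axon", "3" = "basal", "4" = "apical")

#' Read an SWC morphology
#'
#' Parses standard 7-column SWC (`id type x y z radius parent`).  Each
#' non-soma sample becomes one section (the edge from its parent sample to
#' itself); soma samples are merged into a single spherical root whose
#' diameter matches the first soma sample.  Unknown type codes are mapped to
#' `basal` with a warning.
#'
#' @param file path or connection to an SWC file
#' @return a [section_tree()]
#' @export
read_swc <- function(file) {
  lines <- readLines(file)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) stop("empty SWC file")
  m <- do.call(rbind, lapply(strsplit(lines, "[ \t]+"), as.numeric))
  if (ncol(m) != 7) stop("SWC must have 7 columns, found ", ncol(m))
  colnames(m) <- c("id", "type", "x", "y", "z", "r", "parent")
  ids <- m[, "id"]
  if (anyDuplicated(ids)) stop("structural error: duplicate SWC sample id")
  pidx <- match(m[, "parent"], ids)
  orphan <- which(m[, "parent"] != -1 & is.na(pidx))
  if (length(orphan) > 0)
    stop("structural error: sample ", ids[orphan[1]],
         " references missing parent ", m[orphan[1], "parent"])
  types <- as.character(m[, "type"])
  region <- .swc_region[types]
  if (anyNA(region)) {
    warning("unknown SWC type code(s) mapped to 'basal': ",
            paste(unique(types[is.na(region)]), collapse = ", "))
    region[is.na(region)] <- "basal"
  }
  soma_rows <- which(region == "soma")
  if (length(soma_rows) == 0) stop("SWC contains no soma sample")
  soma_d <- 2 * m[soma_rows[1], "r"]
  sec <- list(id = 1L, parent = NA_integer_, parent_frac = 1,
              region = "soma", length = soma_d,
              diam_p = soma_d, diam_d = soma_d,
              x = m[soma_rows[1], "x"], y = m[soma_rows[1], "y"],
              z = m[soma_rows[1], "z"])
  out <- list(as.data.frame(sec))
  ## map SWC sample id -> section id of its distal end
  sec_of <- setNames(rep(1L, length(soma_rows)), ids[soma_rows])
  next_id <- 2L
  ord <- order(ids)   # parents come before children in well-formed SWC,
                      # but resolve by repeated passes to be safe
  todo <- setdiff(ord, soma_rows)
  while (length(todo) > 0) {
    placed <- FALSE
    keep <- integer(0)
    for (i in todo) {
      pkey <- as.character(m[i, "parent"])
      if (is.na(sec_of[pkey])) { keep <- c(keep, i); next }
      placed <- TRUE
      pi <- pidx[i]
      len <- sqrt(sum((m[i, c("x", "y", "z")] - m[pi, c("x", "y", "z")])^2))
      if (len <= 0) len <- 1e-3  # coincident samples: keep a token length
      out[[length(out) + 1L]] <- data.frame(
        id = next_id, parent = sec_of[pkey], parent_frac = 1,
        region = region[i], length = len,
        diam_p = 2 * m[pi, "r"], diam_d = 2 * m[i, "r"],
        x = m[i, "x"], y = m[i, "y"], z = m[i, "z"])
      sec_of[as.character(ids[i])] <- next_id
      next_id <- next_id + 1L
      keep <- setdiff(keep, i)
    }
    if (!placed)
      stop("structural error: cycle involving sample id ", ids[todo[1]])
    todo <- keep
  }
  section_tree(do.call(rbind, out))
}

#' Write a section tree as SWC
#'
#' One SWC sample per section distal end plus one soma sample.  If the tree
#' has no 3D coordinates, straight-line coordinates are synthesized such that
#' inter-sample distances equal section lengths (topology and path distances
#' round-trip exactly; absolute orientation is arbitrary).
#'
#' @param tree a [section_tree()]
#' @param file path to write to
#' @return `file`, invisibly
#' @export
write_swc <- function(tree, file) {
  stopifnot(inherits(tree, "section_tree"))
  tree <- tree[order(tree$id), , drop = FALSE]
  n <- nrow(tree)
  has_xyz <- all(c("x", "y", "z") %in% names(tree)) && !anyNA(tree$x)
  xyz <- matrix(0, n, 3)
  root <- which(is.na(tree$parent))
  if (has_xyz) {
    xyz <- cbind(tree$x, tree$y, tree$z)
  } else {
    ## deterministic directions spreading children apart
    pidx <- match(tree$parent, tree$id)
    for (i in seq_len(n)) {
      if (i == root) next
      ang <- 2.399963229728653 * tree$id[i]          # golden angle
      zc  <- cos(0.7 * tree$id[i]) * 0.3
      dirv <- c(cos(ang) * sqrt(1 - zc^2), sin(ang) * sqrt(1 - zc^2), zc)
      base <- if (pidx[i] == root) c(0, 0, 0) else xyz[pidx[i], ]
      xyz[i, ] <- base + dirv * tree$length[i]
    }
  }
  type_of <- c(soma = 1L, axon = 2L, basal = 3L, apical = 4L)
  swc_id <- seq_len(n)
  swc_parent <- ifelse(is.na(tree$parent), -1L, match(tree$parent, tree$id))
  lines <- sprintf("%d %d %.9f %.9f %.9f %.9f %d",
                   swc_id, type_of[tree$region],
                   xyz[, 1], xyz[, 2], xyz[, 3],
                   ifelse(tree$region == "soma", tree$diam_p / 2, tree$diam_d / 2),
                   swc_parent)
  writeLines(lines, file)
  invisible(file)
}

#' Reference to a point on the morphology
#'
#' @param section section id
#' @param frac arc-length fraction in `[0,1]` along the section
#' @param dist path distance of the point to the soma center (um)
#' @return object of class `site_ref`
#' @export
site_ref <- function(section, frac, dist) {
  stopifnot(frac >= 0, frac <= 1, dist >= 0)
  structure(list(section = section, frac = frac, dist = dist),
            class = "site_ref")
}

#' @export
print.site_ref <- function(x, ...) {
  cat(sprintf("<site> section %s @ %.3f (%.1f um from soma)\n",
              format(x$section), x$frac, x$dist))
  invisible(x)
}

## local diameter of a section at arc fraction f (linear taper)
.diam_at <- function(tree, i, f) tree$diam_p[i] + f * (tree$diam_d[i] - tree$diam_p[i])

#' Select a stimulus site at a given path distance
#'
#' Among all sections of `region` that span `distance`, picks the point at
#' exactly `distance` on the section with the largest local diameter there
#' (the thickest branch); ties are broken by lowest section id.
#'
#' @param tree a [section_tree()]
#' @param region region label
#' @param distance path distance from the soma center (um)
#' @return a [site_ref()]
#' @export
select_site <- function(tree, region, distance) {
  stopifnot(inherits(tree, "section_tree"), distance >= 0)
  cand <- which(tree$region == region &
                tree$dist0 <= distance &
                tree$dist0 + tree$length >= distance)
  if (length(cand) == 0)
    stop("no '", region, "' section at path distance ", distance, " um")
  f <- (distance - tree$dist0[cand]) / tree$length[cand]
  d <- mapply(function(i, fi) .diam_at(tree, i, fi), cand, f)
  ## thickest branch, ties -> lowest id
  best <- cand[order(-d, tree$id[cand])][1]
  site_ref(tree$id[best], (distance - tree$dist0[best]) / tree$length[best],
           distance)
}

#' Discretize a section tree into compartments
#'
#' Splits every section into compartments no longer than `max_len` um (the
#' soma stays one iso-potential spherical compartment).  Membrane areas are
#' frustum lateral areas; axial conductances connect compartment midpoints
#' through the half-compartment resistances on either side.
#'
#' @param tree a [section_tree()]
#' @param max_len maximum compartment length (um); or use `nseg` to force a
#'   per-section compartment count
#' @param nseg optional integer: compartments per section (overrides
#'   `max_len`)
#' @param ra axial resistivity (ohm cm)
#' @return object of class `compartment_graph`: a data.frame with one row per
#'   compartment (`comp`, `parent` \[0 = none\], `section`, `frac_mid`,
#'   `region`, `dist` \[um\], `length` \[um\], `area_cm2`, `g_axial_uS`
#'   \[conductance to parent\]) ordered so that every parent precedes its
#'   children.
#' @export
discretize <- function(tree, max_len = 20, nseg = NULL, ra = 100) {
  stopifnot(inherits(tree, "section_tree"))
  if (!is.null(nseg)) {
    if (nseg < 1) stop("config error: nseg must be >= 1")
  } else if (max_len <= 0) stop("config error: max_len must be > 0")
  root <- which(is.na(tree$parent))
  pidx <- match(tree$parent, tree$id)
  ## order sections root-first
  ord <- root
  remaining <- setdiff(seq_len(nrow(tree)), root)
  while (length(remaining) > 0) {
    nxt <- remaining[pidx[remaining] %in% ord]
    ord <- c(ord, nxt[order(tree$id[nxt])])
    remaining <- setdiff(remaining, nxt)
  }
  soma_d <- tree$diam_p[root]
  comps <- list(data.frame(
    comp = 1L, parent = 0L, section = tree$id[root], frac_mid = 0.5,
    region = "soma", dist = 0, length = soma_d,
    area_cm2 = pi * (soma_d * 1e-4)^2,      # sphere surface
    diam = soma_d, g_axial_uS = 0))
  ## distal-end compartment index of each section, for attaching children
  end_comp <- setNames(rep(NA_integer_, nrow(tree)), tree$id)
  end_comp[as.character(tree$id[root])] <- 1L
  next_comp <- 2L
  ## axial half-resistance (Mohm) of compartment given diam um, half-length um
  half_res <- function(diam_um, halflen_um) {
    ## R = ra * l / A ; ra ohm cm, l cm, A cm^2 -> ohm; report Mohm
    ra * (halflen_um * 1e-4) / (pi * (diam_um * 1e-4 / 2)^2) * 1e-6
  }
  half_res_end <- list()   # per section: half-resistance at prox/dist ends
  half_res_end[[as.character(tree$id[root])]] <- c(0, 0)  # iso-potential soma
  for (i in ord) {
    if (i == root) next
    L <- tree$length[i]
    n <- if (!is.null(nseg)) as.integer(nseg) else max(1L, ceiling(L / max_len))
    seg <- L / n
    f0 <- (seq_len(n) - 1) / n
    f1 <- seq_len(n) / n
    fm <- (f0 + f1) / 2
    d0 <- .diam_at(tree, i, f0); d1 <- .diam_at(tree, i, f1)
    dm <- .diam_at(tree, i, fm)
    r0 <- d0 / 2 * 1e-4; r1 <- d1 / 2 * 1e-4; h <- seg * 1e-4
    area <- pi * (r0 + r1) * sqrt(h^2 + (r0 - r1)^2)  # frustum lateral, cm^2
    ## attach: parent compartment within the parent section at parent_frac
    psec <- pidx[i]
    if (tree$region[psec] == "soma") {
      pc <- end_comp[as.character(tree$id[psec])]
      p_half <- 0
    } else {
      ## compartment of the parent section containing parent_frac
      pc_rows <- which(vapply(comps, function(df) df$section[1] == tree$id[psec],
                              logical(1)))
      pdf <- do.call(rbind, comps[pc_rows])
      k <- pmin(nrow(pdf), pmax(1, ceiling(tree$parent_frac[i] * nrow(pdf))))
      pc <- pdf$comp[k]
      p_half <- half_res(pdf$diam[k], pdf$length[k] / 2)
    }
    ids <- next_comp:(next_comp + n - 1L)
    parents <- c(pc, head(ids, -1))
    hr <- half_res(dm, seg / 2)
    ## conductance to parent: series of parent's distal half + own proximal half
    g_par <- 1 / (c(p_half, head(hr, -1)) + hr)   # 1/Mohm = uS
    comps[[length(comps) + 1L]] <- data.frame(
      comp = ids, parent = parents, section = tree$id[i], frac_mid = fm,
      region = tree$region[i], dist = tree$dist0[i] + fm * L,
      length = seg, area_cm2 = area, diam = dm, g_axial_uS = g_par)
    end_comp[as.character(tree$id[i])] <- ids[n]
    next_comp <- next_comp + n
  }
  g <- do.call(rbind, comps)
  rownames(g) <- NULL
  attr(g, "tree") <- tree
  attr(g, "ra") <- ra
  class(g) <- c("compartment_graph", "data.frame")
  g
}

#' Map a site to its compartment
#'
#' @param graph a [discretize()] result
#' @param site a [site_ref()] or a numeric path distance combined with
#'   `region`
#' @param region region label used when `site` is a distance
#' @return compartment index (row of `graph`)
#' @export
site_compartment <- function(graph, site, region = "apical") {
  stopifnot(inherits(graph, "compartment_graph"))
  if (is.numeric(site))
    site <- select_site(attr(graph, "tree"), region, site)
  rows <- which(graph$section == site$section)
  if (length(rows) == 0) stop("site references unknown section ", site$section)
  rows[which.min(abs(graph$frac_mid[rows] - site$frac))]
}
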