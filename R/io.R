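#' Write a system model to the package's structured-text schema
#'
#' Plain-text key/value + table format with sections `[meta]`, `[box]`,
#' `[atom_types]`, `[atoms]`, `[bonds]`, `[bond_params]`, `[angles]`,
#' `[angle_params]` and (for surrogate targets) `[bond_overrides]` /
#' `[angle_overrides]`.  Numbers are written with 17 significant digits
#' so that `read_system(write_system(x))` reproduces every parameter
#' bit-for-bit.  1-2/1-3 exclusions are re-derived on read.
#'
#' @param model a [system_model()].
#' @param path output file path.
#' @param provenance optional named character vector recorded in
#'   `[meta]` as `prov_<name>` entries.
#' @return `path`, invisibly.
#' @export
write_system <- function(model, path, provenance = NULL) {
  num <- function(x) formatC(x, digits = 17, format = "g")
  ln <- c("# alchemr system schema v1", "[meta]",
          paste0("level = ", model$level),
          paste0("charge_scale = ", num(model$charge_scale)),
          paste0("morse = ", model$morse),
          if (isTRUE(model$morse)) paste0("morse_depth = ", num(model$morse_depth)))
  for (nm in names(provenance))
    ln <- c(ln, paste0("prov_", nm, " = ", provenance[[nm]]))
  ln <- c(ln, "", "[box]",
          paste0("edge = ", if (is.null(model$box_edge)) "none" else
            num(model$box_edge)))

  at <- model$parameters$atom_types
  ln <- c(ln, "", "[atom_types]",
          "name mass charge lj_epsilon lj_rmin_half polarizability drude_spring")
  for (t in at)
    ln <- c(ln, paste(t$name, num(t$mass), num(t$charge), num(t$lj_epsilon),
                      num(t$lj_rmin_half), num(t$polarizability),
                      num(t$drude_spring)))

  a <- model$topology$atoms
  ln <- c(ln, "", "[atoms]", "id type group",
          paste(a$id, a$type, a$group))

  b <- model$topology$bonds
  ln <- c(ln, "", "[bonds]", "i j")
  if (nrow(b)) ln <- c(ln, paste(b[, 1], b[, 2]))
  bp <- model$parameters$bond_params
  ln <- c(ln, "", "[bond_params]", "type_i type_j k_b b0")
  if (nrow(bp)) ln <- c(ln, paste(bp$type_i, bp$type_j, num(bp$k_b), num(bp$b0)))

  an <- model$topology$angles
  ln <- c(ln, "", "[angles]", "i j k")
  if (nrow(an)) ln <- c(ln, paste(an[, 1], an[, 2], an[, 3]))
  ap <- model$parameters$angle_params
  ln <- c(ln, "", "[angle_params]", "type_i type_j type_k k_theta theta0")
  if (nrow(ap)) ln <- c(ln, paste(ap$type_i, ap$type_j, ap$type_k,
                                  num(ap$k_theta), num(ap$theta0)))

  if (!is.null(model$bond_overrides)) {
    bo <- model$bond_overrides
    ln <- c(ln, "", "[bond_overrides]", "bond k_b b0",
            paste(bo$bond, num(bo$k_b), num(bo$b0)))
  }
  if (!is.null(model$angle_overrides)) {
    ao <- model$angle_overrides
    ln <- c(ln, "", "[angle_overrides]", "angle k_theta theta0",
            paste(ao$angle, num(ao$k_theta), num(ao$theta0)))
  }
  if (!is.null(model$frame0)) {
    X <- model$frame0$coordinates
    ln <- c(ln, "", "[coordinates]", "id x y z",
            paste(seq_len(nrow(X)), num(X[, 1]), num(X[, 2]), num(X[, 3])))
  }
  writeLines(ln, path)
  invisible(path)
}

#' @rdname write_system
#' @return `read_system()` returns a [system_model()].
#' @export
read_system <- function(path) {
  ln <- trimws(readLines(path))
  ln <- ln[!startsWith(ln, "#")]
  sec <- cumsum(grepl("^\\[", ln))
  names_sec <- gsub("\\[|\\]", "", ln[grepl("^\\[", ln)])
  chunks <- split(ln, sec)
  chunk_names <- if (0 %in% sec) c("", names_sec) else names_sec
  body <- setNames(lapply(chunks, function(x) x[-1][nzchar(x[-1])]),
                   chunk_names[seq_along(chunks)])

  kv <- function(section) {
    out <- list()
    for (l in body[[section]] %||% character()) {
      p <- strsplit(l, "\\s*=\\s*")[[1]]
      out[[p[1]]] <- p[2]
    }
    out
  }
  tab <- function(section) {
    rows <- body[[section]] %||% character()
    if (length(rows) < 2) return(NULL)
    hdr <- strsplit(rows[1], "\\s+")[[1]]
    vals <- do.call(rbind, strsplit(rows[-1], "\\s+"))
    df <- as.data.frame(vals, stringsAsFactors = FALSE)
    names(df) <- hdr
    df
  }
  meta <- kv("meta")
  box <- kv("box")
  edge <- if (identical(box$edge, "none")) NULL else as.numeric(box$edge)

  tt <- tab("atom_types")
  types <- lapply(seq_len(nrow(tt)), function(k)
    atom_type(tt$name[k], as.numeric(tt$mass[k]), as.numeric(tt$charge[k]),
              as.numeric(tt$lj_epsilon[k]), as.numeric(tt$lj_rmin_half[k]),
              as.numeric(tt$polarizability[k]), as.numeric(tt$drude_spring[k])))
  ta <- tab("atoms")
  atoms <- tibble(id = as.integer(ta$id), type = ta$type, group = ta$group)
  tb <- tab("bonds")
  bonds <- if (is.null(tb)) NULL else cbind(as.integer(tb$i), as.integer(tb$j))
  tan <- tab("angles")
  angles <- if (is.null(tan)) NULL else
    cbind(as.integer(tan$i), as.integer(tan$j), as.integer(tan$k))
  tbp <- tab("bond_params")
  bp <- if (is.null(tbp)) NULL else
    tibble(type_i = tbp$type_i, type_j = tbp$type_j,
           k_b = as.numeric(tbp$k_b), b0 = as.numeric(tbp$b0))
  tap <- tab("angle_params")
  ap <- if (is.null(tap)) NULL else
    tibble(type_i = tap$type_i, type_j = tap$type_j, type_k = tap$type_k,
           k_theta = as.numeric(tap$k_theta), theta0 = as.numeric(tap$theta0))

  m <- system_model(topology(atoms, bonds, angles),
                    parameter_set(types, bp, ap),
                    level = meta$level, box_edge = edge)
  m$charge_scale <- as.numeric(meta$charge_scale %||% 1)
  m$morse <- identical(meta$morse, "TRUE")
  if (m$morse) m$morse_depth <- as.numeric(meta$morse_depth)
  tbo <- tab("bond_overrides")
  if (!is.null(tbo))
    m$bond_overrides <- tibble(bond = as.integer(tbo$bond),
                               k_b = as.numeric(tbo$k_b),
                               b0 = as.numeric(tbo$b0))
  tao <- tab("angle_overrides")
  if (!is.null(tao))
    m$angle_overrides <- tibble(angle = as.integer(tao$angle),
                                k_theta = as.numeric(tao$k_theta),
                                theta0 = as.numeric(tao$theta0))
  tco <- tab("coordinates")
  if (!is.null(tco))
    m$frame0 <- new_frame(cbind(as.numeric(tco$x), as.numeric(tco$y),
                                as.numeric(tco$z)))
  prov <- meta[startsWith(names(meta), "prov_")]
  if (length(prov)) attr(m, "provenance") <- prov
  m
}

#' Write tailored parameter/topology files
#'
#' Serializes a level-MM' model to the package schema with a provenance
#' block (base level, minimizer tolerance if supplied).  The read-back
#' model is energy-equivalent: all parameters round-trip bit-for-bit.
#'
#' @param model_mm_prime a level-MM' [system_model()].
#' @param path output file path.
#' @param minimizer_tol tolerance recorded as provenance, if known.
#' @return `path`, invisibly.
#' @export
write_tailored_files <- function(model_mm_prime, path, minimizer_tol = NULL) {
  if (model_mm_prime$level != "MM'")
    abort("write_tailored_files expects a level-MM' model",
          class = "alchemr_validation")
  prov <- c(base_level = "MM",
            n_unique_types = as.character(
              length(model_mm_prime$parameters$atom_types)))
  if (!is.null(minimizer_tol))
    prov <- c(prov, minimizer_tol = formatC(minimizer_tol, format = "g"))
  write_system(model_mm_prime, path, provenance = prov)
}

#' Read and write multi-frame XYZ files
#'
#' Standard XYZ: an atom-count line, a comment line carrying
#' `step=<n> replica=<r>`, then one `name x y z` line per atom.
#'
#' @param frames a list of [new_frame()]s (or one frame).
#' @param model the [system_model()] supplying atom names.
#' @param path file path.
#' @return `write_xyz()` returns `path` invisibly; `read_xyz()` returns
#'   a list of frames.
#' @export
write_xyz <- function(frames, model, path) {
  if (inherits(frames, "frame")) frames <- list(frames)
  names <- model$topology$atoms$type
  con <- file(path, "w")
  on.exit(close(con))
  for (f in frames) {
    writeLines(as.character(nrow(f$coordinates)), con)
    writeLines(sprintf("step=%d replica=%d", f$step, f$replica_index), con)
    writeLines(sprintf("%s %.10f %.10f %.10f", names,
                       f$coordinates[, 1], f$coordinates[, 2],
                       f$coordinates[, 3]), con)
  }
  invisible(path)
}

#' @rdname write_xyz
#' @export
read_xyz <- function(path) {
  ln <- readLines(path)
  frames <- list()
  i <- 1
  while (i <= length(ln)) {
    n <- as.integer(ln[i])
    cm <- ln[i + 1]
    step <- as.integer(sub(".*step=(\\d+).*", "\\1", cm))
    rep_ <- as.integer(sub(".*replica=(\\d+).*", "\\1", cm))
    rows <- strsplit(trimws(ln[(i + 2):(i + 1 + n)]), "\\s+")
    xyz <- t(vapply(rows, function(r) as.numeric(r[2:4]), numeric(3)))
    frames[[length(frames) + 1]] <-
      new_frame(xyz, replica_index = rep_ %||% 0L, step = step %||% 0L)
    i <- i + 2 + n
  }
  frames
}

#' Write and read per-frame energy logs
#'
#' CSV with one row per frame: `frame`, `step`, `level_A`, `level_B`,
#' `U_A`, `U_B`, `delta_U`, plus one column per energy-breakdown
#' component of the A level.
#'
#' @param log a tibble as produced by the bookend evaluation helpers.
#' @param path file path.
#' @return the tibble (read) or `path` invisibly (write).
#' @export
write_energy_log <- function(log, path) {
  readr::write_csv(log, path)
  invisible(path)
}

#' @rdname write_energy_log
#' @export
read_energy_log <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}
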