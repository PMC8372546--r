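## Multi-frame extended-XYZ reading and writing.
##
## Dialect: Lattice="ax ay az bx by bz cx cy cz",
## Properties=species:S:1:pos:R:3[:forces:R:3][:velocities:R:3],
## energy=<float> and optional pbc="T T F" / time=<fs> in the comment line.

parse_comment_line <- function(line, lineno) {
  kv <- list()
  pat <- '([A-Za-z_][A-Za-z0-9_]*)=("[^"]*"|\\S+)'
  m <- gregexpr(pat, line, perl = TRUE)[[1]]
  if (m[1L] != -1L) {
    starts <- as.integer(m)
    lens <- attr(m, "match.length")
    for (k in seq_along(starts)) {
      tok <- substr(line, starts[k], starts[k] + lens[k] - 1L)
      eq <- regexpr("=", tok, fixed = TRUE)
      key <- substr(tok, 1L, eq - 1L)
      val <- substr(tok, eq + 1L, nchar(tok))
      val <- gsub('^"|"$', "", val)
      kv[[key]] <- val
    }
  }
  kv
}

parse_properties <- function(prop, lineno) {
  if (is.null(prop)) prop <- "species:S:1:pos:R:3"
  toks <- strsplit(prop, ":", fixed = TRUE)[[1]]
  if (length(toks) %% 3L != 0L) {
    stop(sprintf("line %d: malformed Properties string '%s'", lineno, prop))
  }
  n <- length(toks) / 3L
  data.frame(name = toks[3L * seq_len(n) - 2L],
             type = toks[3L * seq_len(n) - 1L],
             ncol = as.integer(toks[3L * seq_len(n)]),
             stringsAsFactors = FALSE)
}

#' Read a multi-frame extended-XYZ file
#'
#' Parses per-frame `Lattice`, `Properties` (species, positions, optionally
#' forces and velocities) and the `energy` key from the comment line.
#' Missing optional fields are left absent.
#'
#' @param path path to an extended-XYZ file.
#' @return a `configuration_set`.
#' @export
read_extxyz <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  configs <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat) || nat < 1L ||
        trimws(lines[i]) != as.character(nat)) {
      stop(sprintf("line %d: malformed atom count line '%s'", i, lines[i]))
    }
    if (i + 1L + nat > length(lines)) {
      stop(sprintf("line %d: frame claims %d atoms but file ends early", i, nat))
    }
    kv <- parse_comment_line(lines[i + 1L], i + 1L)
    props <- parse_properties(kv$Properties, i + 1L)
    ncol_total <- sum(props$ncol)

    body <- lines[(i + 2L):(i + 1L + nat)]
    toks <- strsplit(trimws(body), "[[:space:]]+")
    nt <- lengths(toks)
    if (any(nt != ncol_total)) {
      bad <- which(nt != ncol_total)[1L]
      stop(sprintf("line %d: expected %d columns, found %d",
                   i + 1L + bad, ncol_total, nt[bad]))
    }
    tok_mat <- do.call(rbind, toks)

    col <- 1L
    species <- NULL; pos <- NULL; forces <- NULL; velocities <- NULL
    for (p in seq_len(nrow(props))) {
      cols <- col:(col + props$ncol[p] - 1L)
      block <- tok_mat[, cols, drop = FALSE]
      nm <- props$name[p]
      if (nm == "species") {
        species <- as.character(block[, 1L])
      } else if (props$type[p] == "R" || props$type[p] == "I") {
        num <- suppressWarnings(matrix(as.numeric(block), nrow = nat))
        if (anyNA(num)) {
          bad <- which(apply(is.na(num), 1L, any))[1L]
          stop(sprintf("line %d: non-numeric value in property '%s'",
                       i + 1L + bad, nm))
        }
        if (nm == "pos") pos <- num
        if (nm == "forces") forces <- num
        if (nm == "velocities") velocities <- num
      }
      col <- col + props$ncol[p]
    }
    if (is.null(species) || is.null(pos)) {
      stop(sprintf("line %d: frame lacks species/pos properties", i + 1L))
    }
    if (!all(is_element_symbol(species))) {
      bad <- which(!is_element_symbol(species))[1L]
      stop(sprintf("line %d: '%s' is not an element symbol",
                   i + 1L + bad, species[bad]))
    }

    cell <- NULL; pbc <- c(FALSE, FALSE, FALSE)
    if (!is.null(kv$Lattice)) {
      v <- as.numeric(strsplit(trimws(kv$Lattice), "[[:space:]]+")[[1]])
      if (length(v) != 9L || anyNA(v)) {
        stop(sprintf("line %d: malformed Lattice", i + 1L))
      }
      cell <- matrix(v, 3L, 3L, byrow = TRUE)
      pbc <- c(TRUE, TRUE, TRUE)
    }
    if (!is.null(kv$pbc)) {
      pbc <- toupper(strsplit(trimws(kv$pbc), "[[:space:]]+")[[1]]) %in% c("T", "TRUE")
      if (length(pbc) != 3L) stop(sprintf("line %d: malformed pbc", i + 1L))
    }
    energy <- if (!is.null(kv$energy)) as.numeric(kv$energy) else NULL
    info <- list()
    if (!is.null(kv$time)) info$time <- as.numeric(kv$time)
    if (!is.null(kv$image)) info$image <- as.integer(kv$image)
    level_tag <- if (!is.null(kv$level_tag)) kv$level_tag else NULL

    configs[[length(configs) + 1L]] <- configuration(
      species = species, positions = pos, cell = cell, pbc = pbc,
      energy = energy, forces = forces, velocities = velocities,
      level_tag = level_tag, info = info)
    i <- i + 2L + nat
  }
  configuration_set(configs)
}

fmt_num <- function(x) sprintf("%.16g", x)

#' Write configurations to an extended-XYZ file
#'
#' Frames are concatenated; `energy=` is written in the comment line and
#' forces/velocities as per-atom property blocks, at full double precision.
#'
#' @param set a `configuration_set` (or a single `configuration`).
#' @param path output file path.
#' @return invisibly, the path.
#' @export
write_extxyz <- function(set, path) {
  set <- configuration_set(set)
  out <- character(0)
  for (cfg in unclass(set)) {
    props <- "species:S:1:pos:R:3"
    if (!is.null(cfg$forces)) props <- paste0(props, ":forces:R:3")
    if (!is.null(cfg$velocities)) props <- paste0(props, ":velocities:R:3")
    comment <- sprintf("Properties=%s", props)
    if (!is.null(cfg$cell)) {
      comment <- sprintf('Lattice="%s" %s',
                         paste(fmt_num(as.vector(t(cfg$cell))), collapse = " "),
                         comment)
      comment <- paste0(comment, sprintf(' pbc="%s"',
                        paste(ifelse(cfg$pbc, "T", "F"), collapse = " ")))
    }
    if (!is.null(cfg$energy)) {
      comment <- paste0(comment, sprintf(" energy=%s", fmt_num(cfg$energy)))
    }
    if (!is.null(cfg$info$time)) {
      comment <- paste0(comment, sprintf(" time=%s", fmt_num(cfg$info$time)))
    }
    if (!is.null(cfg$info$image)) {
      comment <- paste0(comment, sprintf(" image=%d", cfg$info$image))
    }
    if (!is.null(cfg$level_tag)) {
      comment <- paste0(comment, sprintf(' level_tag="%s"', cfg$level_tag))
    }
    rows <- cbind(cfg$positions,
                  if (!is.null(cfg$forces)) cfg$forces,
                  if (!is.null(cfg$velocities)) cfg$velocities)
    body <- paste(cfg$species,
                  apply(rows, 1L, function(r) paste(fmt_num(r), collapse = " ")))
    out <- c(out, as.character(n_atoms(cfg)), comment, body)
  }
  writeLines(out, path)
  invisible(path)
}

#' Write a trajectory as extended-XYZ with `time=` comments
#'
#' @param traj a `trajectory`.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
write_trajectory_extxyz <- function(traj, path) {
  frames <- unclass(traj$frames)
  for (k in seq_along(frames)) frames[[k]]$info$time <- traj$times[k]
  write_extxyz(configuration_set(frames), path)
}
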