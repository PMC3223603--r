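# ---- SDF (V2000) with a pharmacophore-feature data tag --------------------
#
# Feature tag dialect: data item "PHARMACOPHORE_FEATURES"; first line is the
# feature count; each following line is "k a1 ... ak type" with k member
# atoms (1-based indices into the molfile atom block) and type one of
# acceptor, anion, cation, donor, hydrophobe, rings.  Feature positions are
# the member-atom centroids.  "rings" is accepted as an alias of "ring".

format_feature_block <- function(feats) {
  if (nrow(feats) == 0L) return("0")
  lines <- vapply(seq_len(nrow(feats)), function(i) {
    m <- feats$members[[i]]
    t <- feats$ftype[i]
    if (t == "ring") t <- "rings"
    paste(c(length(m), m, t), collapse = " ")
  }, character(1))
  c(as.character(nrow(feats)), lines)
}

parse_feature_block <- function(lines, atom_xyz) {
  n <- suppressWarnings(as.integer(lines[1]))
  if (is.na(n)) stop("malformed feature tag: bad count line")
  if (n == 0L) return(feature_points())
  body <- lines[-1][seq_len(n)]
  ftype <- character(n)
  members <- vector("list", n)
  for (i in seq_len(n)) {
    tok <- strsplit(trimws(body[i]), "\\s+")[[1]]
    k <- as.integer(tok[1])
    members[[i]] <- as.integer(tok[1 + seq_len(k)])
    t <- tok[k + 2L]
    if (t == "rings") t <- "ring"
    ftype[i] <- t
  }
  idx <- unlist(members)
  if (any(idx < 1L) || any(idx > nrow(atom_xyz)))
    stop("feature member atom index out of range")
  feature_points(ftype, members = members, atom_xyz = atom_xyz)
}

#' Write conformers to an SDF (V2000) file
#'
#' Emits one molfile record per conformer: atom block (4-decimal
#' coordinates), a chain bond block connecting successive atoms (synthetic
#' conformers are chains; the bond block is informational only), the
#' `PHARMACOPHORE_FEATURES` data item, and a `CID` data item.  Writers are
#' deterministic: identical inputs produce byte-identical files.
#'
#' @param conformers List of [conformer()] objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sdf <- function(conformers, path) {
  out <- unlist(lapply(conformers, function(conf) {
    n <- nrow(conf$xyz)
    nb <- max(n - 1L, 0L)
    atoms <- vapply(seq_len(n), function(i)
      sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
              conf$xyz[i, 1], conf$xyz[i, 2], conf$xyz[i, 3],
              conf$elements[i]), character(1))
    bonds <- if (nb) vapply(seq_len(nb), function(i)
      sprintf("%3d%3d  1  0", i, i + 1L), character(1)) else character()
    c(sprintf("CID%d", conf$cid),
      "  combotan",
      "",
      sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb),
      atoms, bonds,
      "M  END",
      "> <PHARMACOPHORE_FEATURES>",
      format_feature_block(conf$features),
      "",
      "> <CID>",
      as.character(conf$cid),
      "",
      "$$$$")
  }))
  writeLines(out, path)
  invisible(path)
}

#' Read conformers from an SDF (V2000) file
#'
#' Parses with ChemmineR, drops hydrogens (and any feature referencing a
#' dropped atom, with a warning), reads features from the
#' `PHARMACOPHORE_FEATURES` data item when present, and takes the cid from
#' the `CID` data item, falling back to the record's position in the file.
#' Malformed records are skipped with a warning and counted in the
#' `n_skipped` attribute.
#'
#' @param path SDF file path.
#' @return List of [conformer()] objects with attribute `n_skipped`.
#' @export
read_sdf <- function(path) {
  if (!file.exists(path)) stop("cannot read ", path)
  if (any(grepl("V3000", readLines(path, warn = FALSE), fixed = TRUE)))
    stop("V3000 records are unsupported")
  sdfset <- suppressWarnings(ChemmineR::read.SDFset(path))
  n_skipped <- 0L
  out <- list()
  for (i in seq_along(sdfset)) {
    conf <- tryCatch(sdf_record_to_conformer(sdfset[[i]], fallback_cid = i),
                     error = function(e) {
                       warning(sprintf("skipping SDF record %d: %s", i,
                                       conditionMessage(e)))
                       NULL
                     })
    if (is.null(conf)) n_skipped <- n_skipped + 1L
    else out[[length(out) + 1L]] <- conf
  }
  attr(out, "n_skipped") <- n_skipped
  out
}

sdf_record_to_conformer <- function(sdf, fallback_cid) {
  ab <- ChemmineR::atomblock(sdf)
  xyz <- unname(ab[, 1:3, drop = FALSE])
  elements <- sub("_.*$", "", rownames(ab))
  heavy <- elements != "H"
  # map original indices to heavy-only indices (0 = dropped)
  remap <- integer(length(heavy))
  remap[heavy] <- seq_len(sum(heavy))
  xyz_h <- xyz[heavy, , drop = FALSE]
  db <- ChemmineR::datablock(sdf)
  feats <- feature_points()
  if ("PHARMACOPHORE_FEATURES" %in% names(db)) {
    lines <- strsplit(db[["PHARMACOPHORE_FEATURES"]], " __ ", fixed = TRUE)[[1]]
    feats <- parse_feature_block(lines, xyz)
    if (nrow(feats)) {
      on_heavy <- vapply(feats$members, function(m) all(heavy[m]), logical(1))
      if (!all(on_heavy)) {
        warning("dropping feature(s) anchored on hydrogen atoms")
        feats <- feats[on_heavy, , drop = FALSE]
      }
      if (nrow(feats))
        feats <- feature_points(feats$ftype,
                                members = lapply(feats$members,
                                                 function(m) remap[m]),
                                atom_xyz = xyz_h,
                                radius = if (nrow(feats)) feats$radius[1] else 1)
      else feats <- feature_points()
    }
  }
  cid <- if ("CID" %in% names(db)) as.integer(db[["CID"]]) else fallback_cid
  conf <- conformer(cid, xyz_h, elements[heavy], feats)
  bb <- tryCatch(ChemmineR::bondblock(sdf), error = function(e) NULL)
  attr(conf, "rotor_estimate") <- estimate_rotors(bb, heavy, remap, nrow(xyz_h))
  conf
}

# Effective-rotor estimate from a molfile bond block: acyclic (bridge),
# non-terminal single bonds between heavy atoms.
estimate_rotors <- function(bondblock, heavy, remap, n_heavy) {
  if (is.null(bondblock) || nrow(bondblock) == 0L || n_heavy < 2L) return(0L)
  a <- as.integer(bondblock[, 1]); b <- as.integer(bondblock[, 2])
  order_ <- as.integer(bondblock[, 3])
  keep <- heavy[a] & heavy[b] & order_ == 1L
  if (!any(keep)) return(0L)
  a <- remap[a[keep]]; b <- remap[b[keep]]
  g <- igraph::graph_from_edgelist(cbind(a, b), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n_heavy - igraph::vcount(g)))
  deg <- igraph::degree(g)
  br <- igraph::bridges(g)
  ends <- igraph::ends(g, br)
  sum(deg[ends[, 1]] > 1L & deg[ends[, 2]] > 1L)
}

# ---- assay CSV ------------------------------------------------------------

#' Read assay outcome tables from CSV
#'
#' Expects columns `aid, cid, outcome, assay_type` (header required) and
#' groups rows into one [assay_table()] per AID.  Unknown or blank assay
#' types become `"unspecified"`; duplicate (aid, cid) rows resolve by the
#' noninactive-wins rule with a warning.
#'
#' @param path CSV file path.
#' @return List of [assay_table()] objects, ordered by AID.
#' @export
read_assays <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("aid", "cid", "outcome", "assay_type")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  df$assay_type <- tolower(trimws(df$assay_type))
  df$assay_type[!df$assay_type %in% ASSAY_CATEGORIES] <- "unspecified"
  lapply(split(df, df$aid), function(sub)
    assay_table(sub$aid[1], sub$assay_type[1], sub$cid, sub$outcome))
}

#' Write an assay collection to CSV
#'
#' @param assays List of [assay_table()] objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_assays <- function(assays, path) {
  rows <- do.call(rbind, lapply(assays, function(a)
    data.frame(aid = a$aid, cid = as.integer(names(a$outcomes)),
               outcome = unname(a$outcomes), assay_type = a$category)))
  write.csv_det(rows, path)
  invisible(path)
}

# ---- TSV writers ----------------------------------------------------------

write.csv_det <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' Write a similarity score table as TSV
#'
#' Scores are serialized at 4 decimal places and pose entries at 6
#' (half-even rounding); internal values are never rounded.  Rows are
#' sorted by `(cid_a, cid_b)` so identical runs give byte-identical files.
#'
#' @param scores Table from [score_matrix()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path) {
  scores <- scores[order(scores$cid_a, scores$cid_b), , drop = FALSE]
  for (m in intersect(MEASURES, names(scores)))
    scores[[m]] <- sprintf("%.4f", scores[[m]])
  tf_cols <- grep("^(stopt|ctopt)_", names(scores), value = TRUE)
  for (col in tf_cols) scores[[col]] <- sprintf("%.6f", scores[[col]])
  write.table(scores, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a similarity score table from TSV
#'
#' @param path TSV written by [write_scores()].
#' @return Data frame with numeric score (and pose, when present) columns.
#' @export
read_scores <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Write a descriptor table as TSV
#'
#' @param descriptors Row-bound [conformer_descriptors()] output.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_descriptors <- function(descriptors, path) {
  descriptors <- descriptors[order(descriptors$cid), , drop = FALSE]
  num <- c("volume", "qx", "qy", "qz")
  for (col in num) descriptors[[col]] <- sprintf("%.4f", descriptors[[col]])
  write.table(descriptors, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
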