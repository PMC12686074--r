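#' Read an atomic structure model (PDB or mmCIF)
#'
#' Parses a PDB or mmCIF file into a tidy atom table. Multi-model files
#' (e.g. NMR-style `MODEL` blocks or a written coordinate ensemble) yield
#' one block of rows per model, distinguished by the `model` column.
#' Hydrogens are retained in the table but ignored by every geometry
#' operation (predicted models are heavy-atom reliable at best).
#'
#' @param path Path to a `.pdb` or `.cif` file.
#' @return A `structure_model`: list with `atoms` (tibble: `model`,
#'   `eleno`, `elety`, `resid`, `chain`, `resno`, `het`, `element`, `x`,
#'   `y`, `z`) and `n_models`.
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) abort(sprintf("Structure file not found: %s", path))
  is_cif <- grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE)
  pdb <- if (is_cif) suppressWarnings(bio3d::read.cif(path)) else
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE))
  if (is.null(pdb$atom) || nrow(pdb$atom) == 0L) {
    abort(sprintf("No atoms parsed from %s", path))
  }
  atoms1 <- tibble(
    eleno = pdb$atom$eleno,
    elety = pdb$atom$elety,
    resid = pdb$atom$resid,
    chain = ifelse(is.na(pdb$atom$chain), "A", pdb$atom$chain),
    resno = pdb$atom$resno,
    het = pdb$atom$type == "HETATM",
    element = guess_element(pdb$atom$elety, pdb$atom$elesy)
  )
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  n_models <- nrow(xyz)
  atoms <- purrr::map_dfr(seq_len(n_models), function(m) {
    co <- matrix(xyz[m, ], ncol = 3, byrow = TRUE)
    bind_cols(tibble(model = m), atoms1,
              tibble(x = co[, 1], y = co[, 2], z = co[, 3]))
  })
  if (any(!is.finite(c(atoms$x, atoms$y, atoms$z)))) {
    abort(sprintf("Non-finite coordinates in %s", path))
  }
  new_structure_model(atoms, id = basename(path))
}

guess_element <- function(elety, elesy = NULL) {
  if (!is.null(elesy) && !all(is.na(elesy)) && !all(elesy == "")) {
    el <- toupper(trimws(elesy))
    el[el == "" | is.na(el)] <- NA_character_
    fallback <- substr(gsub("[^A-Za-z]", "", elety), 1, 1)
    return(toupper(ifelse(is.na(el), fallback, el)))
  }
  toupper(substr(gsub("[^A-Za-z]", "", elety), 1, 1))
}

new_structure_model <- function(atoms, id = "model") {
  structure(list(id = id, atoms = atoms,
                 n_models = max(atoms$model)),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  a1 <- x$atoms[x$atoms$model == 1L, ]
  cat(sprintf("<structure_model> %s: %d model(s), %d atoms, %d residues, chains: %s\n",
              x$id, x$n_models, nrow(a1),
              nrow(distinct(a1, .data$chain, .data$resno)),
              paste(unique(a1$chain), collapse = ",")))
  invisible(x)
}

#' Write a structure model to PDB
#'
#' Writes all models of a `structure_model` as a (possibly multi-model)
#' PDB file via [bio3d::write.pdb()].
#'
#' @param model A `structure_model`.
#' @param path Output `.pdb` path.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(model, path) {
  stopifnot(inherits(model, "structure_model"))
  a1 <- model$atoms[model$atoms$model == 1L, ]
  xyz <- t(vapply(seq_len(model$n_models), function(m) {
    am <- model$atoms[model$atoms$model == m, ]
    as.vector(t(as.matrix(am[, c("x", "y", "z")])))
  }, numeric(3L * nrow(a1))))
  bio3d::write.pdb(
    file = path, xyz = xyz,
    type = ifelse(a1$het, "HETATM", "ATOM"),
    resno = a1$resno, resid = a1$resid, chain = a1$chain,
    elety = a1$elety, eleno = a1$eleno
  )
  invisible(path)
}

heavy_atoms <- function(model, m = 1L) {
  filter(model$atoms, .data$model == m, .data$element != "H")
}

coords_matrix <- function(atoms) {
  as.matrix(atoms[, c("x", "y", "z")])
}
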