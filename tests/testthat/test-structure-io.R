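test_that("rna_structure validates inputs", {
  P <- C4 <- N <- matrix(0, 2, 3)
  expect_s3_class(rna_structure("A", "AG", P, C4, N), "rna_structure")
  expect_error(rna_structure("A", "AXG", matrix(0, 3, 3), matrix(0, 3, 3),
                             matrix(0, 3, 3)))
  expect_error(rna_structure("A", "AG", P, C4, matrix(c(NA, 0, 0, 0, 0, 0), 2, 3)),
               "non-finite")
  # missing atoms may carry non-finite placeholders when flagged absent
  ok <- matrix(TRUE, 2, 3); ok[1, 3] <- FALSE
  st <- rna_structure("A", "AG", P, C4, matrix(c(NaN, 0, 0, 0, 0, 0), 2, 3),
                      atom_ok = ok)
  expect_equal(length(st), 2L)
})

test_that("a minimal hand-written PDB parses to the right chain record", {
  st <- parse_structure(single_g_pdb(), "A")
  expect_equal(st$sequence, "G")
  expect_equal(length(st), 1L)
  expect_true(all(st$atom_ok))
  expect_equal(st$C4[1, ], c(3, 1, 0))
  expect_equal(st$N[1, ], c(5.5, 0.5, 1))
  expect_error(parse_structure(single_g_pdb(), "B"), "chain 'B' not found")
})

test_that("synthetic structures round-trip through PDB text", {
  hp <- make_hairpin(3, 4, seed = 7)
  txt <- write_pdb_structure(hp$structure)
  st <- parse_structure(txt, "A")
  expect_equal(st$sequence, hp$structure$sequence)
  expect_equal(st$C4, hp$structure$C4, tolerance = 1e-3)
  expect_equal(st$P, hp$structure$P, tolerance = 1e-3)
  expect_equal(st$N, hp$structure$N, tolerance = 1e-3)
  expect_equal(st$residue_numbers, seq_len(length(st)))
})

test_that("altloc resolves to the highest-occupancy conformer", {
  mk <- function(serial, name, alt, x, occ) {
    sprintf("ATOM  %5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            serial, name, alt, "G", "A", 1L, x, 0, 0, occ, 0, substr(name, 1, 1))
  }
  txt <- paste(c(mk(1, "P", " ", 0, 1.0),
                 mk(2, "C4'", "A", 1, 0.4),
                 mk(3, "C4'", "B", 2, 0.6),
                 mk(4, "N9", " ", 5, 1.0),
                 "END"), collapse = "\n")
  st <- parse_structure(txt, "A", format = "pdb")
  expect_equal(st$C4[1, 1], 2)   # occupancy 0.6 wins
})

test_that("modified residues map to N; non-nucleotides are dropped; missing P flagged", {
  lines <- c(
    # residue 1: pseudouridine-like, has C4' and N1, no P
    "ATOM      1  C4' PSU A   1       1.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  N1  PSU A   1       4.000   0.000   0.000  1.00  0.00           N",
    # an ion and a protein-like residue: no C4'/glycosidic N -> dropped
    "HETATM    3 MG   MG  A  90      10.000  10.000  10.000  1.00  0.00          MG",
    "ATOM      4  CA  ALA A  91      20.000  20.000  20.000  1.00  0.00           C",
    # residue 2: normal A
    "ATOM      5  P   A   A   2       0.000   5.000   0.000  1.00  0.00           P",
    "ATOM      6  C4' A   A   2       3.000   5.000   0.000  1.00  0.00           C",
    "ATOM      7  N9  A   A   2       6.000   5.000   0.000  1.00  0.00           N",
    "END")
  st <- parse_structure(lines, "A")
  expect_equal(st$sequence, "NA")
  expect_equal(length(st), 2L)
  expect_false(st$atom_ok[1, 1])           # missing P
  expect_true(all(st$atom_ok[2, ]))
  expect_equal(st$residue_numbers, c(1L, 2L))
})

test_that("a minimal mmCIF atom_site loop parses", {
  cif <- c("data_test", "loop_",
           "_atom_site.group_PDB", "_atom_site.id", "_atom_site.auth_atom_id",
           "_atom_site.auth_comp_id", "_atom_site.auth_asym_id",
           "_atom_site.auth_seq_id", "_atom_site.Cartn_x", "_atom_site.Cartn_y",
           "_atom_site.Cartn_z", "_atom_site.occupancy",
           "ATOM 1 P   G B 1 0.0 0.0 0.0 1.0",
           "ATOM 2 \"C4'\" G B 1 3.0 1.0 0.0 1.0",
           "ATOM 3 N9  G B 1 5.5 0.5 1.0 1.0",
           "ATOM 4 P   C B 2 0.0 9.0 0.0 1.0",
           "ATOM 5 \"C4'\" C B 2 3.0 9.0 0.0 1.0",
           "ATOM 6 N1  C B 2 6.0 9.0 0.0 1.0",
           "#")
  st <- parse_structure(cif, "B")      # auto-detects mmCIF
  expect_equal(st$sequence, "GC")
  expect_equal(st$C4[2, ], c(3, 9, 0))
  expect_true(all(st$atom_ok))
})

test_that("basepair_set normalises, deduplicates and validates", {
  bp <- basepair_set(rbind(c(9, 2), c(2, 9), c(1, 5)), 10)
  expect_equal(bp$pairs, rbind(c(1L, 5L), c(2L, 9L)))
  expect_error(basepair_set(rbind(c(3, 3)), 10), "self-pair")
  expect_error(basepair_set(rbind(c(1, 11)), 10), "out of range")
  expect_equal(nrow(basepair_set(NULL, 10)$pairs), 0L)
})

test_that("pairs TSV reading handles comments and reports malformed lines", {
  txt <- "# stem\n1\t9\n2 8\n\n3\t7 # inner\n"
  bp <- read_basepairs(txt, "tsv", 10)
  expect_equal(bp$pairs, rbind(c(1L, 9L), c(2L, 8L), c(3L, 7L)))
  expect_error(read_basepairs("1\t9\nfoo bar\n", "tsv", 10),
               "malformed pair line 2")
  expect_error(read_basepairs("1 20\n", "tsv", 10), "out of range")
})

test_that("DSSR-style JSON pairs parse with residue-number mapping and LW tags", {
  js <- '{"pairs":[{"nt1":"A.G4","nt2":"A.C12","LW":"cWW"},
                   {"nt1":"A.U5","nt2":"A.A11","LW":"tHS"}]}'
  bp <- read_basepairs(js, "dssr", 6, residue_numbers = c(3L, 4L, 5L, 10L, 11L, 12L))
  expect_equal(bp$pairs, rbind(c(2L, 6L), c(3L, 5L)))
  expect_equal(bp$class_label, c("cWW", "tHS"))
  expect_error(read_basepairs(js, "dssr", 6, residue_numbers = c(1:5, 99L)),
               "absent from the chain")
  expect_equal(nrow(read_basepairs('{"pairs":[]}', "dssr", 6)$pairs), 0L)
})

test_that("FASTA writing wraps, validates and round-trips", {
  s <- paste(rep("ACGU", 40), collapse = "")   # 160 nt
  txt <- write_fasta(c(long = s, short = "ACGUN"))
  lines <- strsplit(txt, "\n")[[1]]
  expect_equal(lines[1], ">long")
  expect_true(all(nchar(lines[2:4]) == c(60, 60, 40)))
  back <- read_fasta(txt)
  expect_equal(back, c(long = s, short = "ACGUN"))
  expect_error(write_fasta(c(bad = "ACGTZ")), "illegal character 'T' at position 4")
  expect_error(read_fasta("no header"), "does not start with '>'")
})

test_that("pairs TSV writer round-trips", {
  bp <- basepair_set(rbind(c(1, 9), c(2, 8)), 10)
  txt <- write_pairs_tsv(bp)
  expect_equal(read_basepairs(txt, "tsv", 10)$pairs, bp$pairs)
  expect_equal(write_pairs_tsv(basepair_set(NULL, 5)), "")
})

test_that("conformer_group enforces a shared length", {
  a <- make_hairpin(3, 4, seed = 1)
  b <- make_hairpin(3, 5, seed = 1)
  expect_error(conformer_group(list(list(structure = a$structure, pairs = a$pairs),
                                    list(structure = b$structure, pairs = b$pairs))),
               "share one sequence length")
  g <- conformer_group(list(list(structure = a$structure, pairs = a$pairs)))
  expect_equal(g$sequence, a$structure$sequence)
})
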