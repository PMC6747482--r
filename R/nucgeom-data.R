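# Idealized nucleotide geometry used by the synthetic fixture generators.
#
# Derived once from an idealized construction: planar base rings (regular
# polygons, ring bond 1.39/1.38 A), Watson-Crick pair frame with C1' atoms
# 10.4 A apart and glycosidic bonds at lambda = 54.5 deg, and a shared
# sugar/phosphate set built from ideal bond lengths and 1-3 distances by
# trilateration, with the phosphate positioned so that the A-form helical
# step operator (twist 32.7 deg, rise 2.81 A, axis = z) closes the
# O3'(i)-P(i+1) bond at exactly 1.60 A on both strands.  Coordinates are in
# the base-pair frame of the 5' strand; the partner strand of a pair is the
# 180-degree rotation about the y axis (a proper rotation, preserving sugar
# chirality).  This is a self-consistent synthetic geometry, not fiber
# diffraction data.

.HELIX_TWIST <- 0.5707226654   # radians (32.7 degrees)
.HELIX_RISE  <- 2.810000    # Angstrom

# sugar + phosphate, shared by all four bases (strand-1 site)
.SUGAR_XYZ <- matrix(c(
    -5.200000, 0.000000, 0.000000,
    -6.542855, 0.211473, 0.702082,
    -7.434287, -0.764327, -0.048626,
    -6.476680, -1.366479, -1.078820,
    -5.496396, -0.331063, -1.342365,
    -7.952529, -1.729499, 0.859558,
    -6.379842, -0.622393, -2.389186,
    -7.432864, 0.355147, -2.484895,
    -7.706126, 1.382068, -1.298131
  ), ncol = 3, byrow = TRUE,
  dimnames = list(c("C1'", "C2'", "C3'", "C4'", "O4'", "O3'", "C5'", "O5'", "P"), c("x", "y", "z")))

# purine ring (A, G), strand-1 site; glycosidic atom N9
.PURINE_XYZ <- matrix(c(
    -4.340560, 1.204891, 0.000000,
    -3.946549, 2.527447, 0.000000,
    -2.566967, 2.561413, 0.000000,
    -2.108349, 1.259849, 0.000000,
    -3.204490, 0.421472, 0.000000,
    -3.037044, -0.949582, 0.000000,
    -1.767357, -1.496524, 0.000000,
    -0.653713, -0.677348, 0.000000,
    -0.797739, 0.697609, 0.000000
  ), ncol = 3, byrow = TRUE,
  dimnames = list(c("N9", "C8", "N7", "C5", "C4", "N3", "C2", "N1", "C6"), c("x", "y", "z")))

# pyrimidine ring (C, U), strand-1 site; glycosidic atom N1
.PYRIMIDINE_XYZ <- matrix(c(
    -4.340560, 1.204891, 0.000000,
    -2.952407, 1.276533, 0.000000,
    -2.196287, 0.110179, 0.000000,
    -2.828319, -1.127817, 0.000000,
    -4.216472, -1.199460, 0.000000,
    -4.972592, -0.033106, 0.000000
  ), ncol = 3, byrow = TRUE,
  dimnames = list(c("N1", "C2", "N3", "C4", "C5", "C6"), c("x", "y", "z")))

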