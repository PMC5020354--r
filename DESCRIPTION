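Package: guvflim
Title: Polarized FLIM Analysis of Single Giant Unilamellar Vesicles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Determines the mean orientation of fluorophore transition dipoles
    with respect to the membrane normal of a giant unilamellar vesicle (GUV)
    from two-channel polarized confocal fluorescence lifetime images of its
    equatorial cross-section. A closed-form photoselection model converts the
    lifetime-weighted ratio of fluorescence pooled over membrane sectors
    perpendicular to the Z and Y image axes into the dipole cone angle.
    Time-correlated single photon counting (TCSPC) decays are decomposed by
    Poisson maximum likelihood into free or library-constrained exponential
    mixtures, quantifying amphotericin B organization forms (tetramer 0.35 ns,
    parallel dimer 1.8 ns, monomer 3.0 ns, antiparallel dimer 6.8 ns), with
    G-factor corrected steady-state and time-resolved anisotropy. A
    ground-truthed forward simulator (photoselection ring, polarized channel
    split, exponential-mixture arrival times, Poisson noise, Gaussian PSF)
    makes every stage verifiable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    pracma,
    tiff,
    jsonlite,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
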