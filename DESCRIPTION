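Package: holofocus
Title: Holographic Acoustic Lens Design for Multifocal Transcranial
    Ultrasound
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Design, validation and dosimetry tools for 3D-printable
    acoustic holographic lenses that focus a single-element ultrasound
    transducer onto several transcranial targets at once.  The package
    implements monochromatic Rayleigh-Sommerfeld propagation, time-reversal
    recording of virtual sources placed at the desired foci (through a
    flat skull layer modelled as a fluid slab), inversion of the slab
    transmission coefficient into a per-pixel lens height map with
    print-resolution quantization, a forward simulator that verifies the
    multifocal field, and pulse-scheme arithmetic for the safety indices
    (duty cycle, Ispta, mechanical index) of the stimulation waveform.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
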