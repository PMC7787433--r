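# UniProt inputs (user-supplied)

The sequence-characterization checks of the two study regions run on the
real UniProt records, which are not redistributed with the package.
To enable them, download and place here:

  - `Q9Y6I3.fasta` — human Epsin-1 (analyzed region: residues 232-471)
  - `P42566.fasta` — human Eps15   (analyzed region: residues 498-830)

e.g. from https://rest.uniprot.org/uniprotkb/Q9Y6I3.fasta and
https://rest.uniprot.org/uniprotkb/P42566.fasta, then reinstall the
package. All other functionality is independent of these files.
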