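>rpsl_ref_synthetic synthetic RpsL stand-in, K42/K87 validated (E. coli-style numbering)
MIFPRDEDRRKVMVHKPRMVRYQELEKFRGAMMNRLCPTLCKSVPSKNGTPLGHRCDLRRKWSRHKMTEY
FCKRGWRVQEPKYQVTKRRMYQKKLGILRKRIGANVFAWVYNQKFKNYVIYNWT
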