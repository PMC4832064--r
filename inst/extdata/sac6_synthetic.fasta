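>sac6_synthetic synthetic stand-in for full-length Sac6; real loop segment at 99-125; engineered minimal S/T-P sites at 103, 366, 589
ADFIRVQRFLKVEFRCMDHNKLKHQMNEWIQALHEQIICHKYKKNQYGIRVVHCKCQEVY
DCWIFQVMQFIIGIFLLNLAALMVMNDWRAHVEYHDKKAPNSTPIVSTAATGLQHKGKGT
QAKIIQFGVCMAMGMYKEKKCFHYGQNAVCQHMNDDEIFRDDNYHHEGEDNEEWWWQKEL
HWLWKGCLKMQFHHEGHAMQERFCGNNACVCNVHVWGCYAKIWCACMKVIGEMVGWFNFQ
KERAGRLHRQCRELDMIEHIMAGMNMAMVNFQKIFDMDVLCWMDHWWCKHRGCMIAQWYD
CEKEIEYIMVRDFEDAMFCAHWGNGNHFKRKHFLWRRFWQQEWIMADQVVIRYVRRHGCM
HKFGHTPVAVQQWYACREHYLMNFLGNNFIWLDNWRMVGHLGQNFRLKAAEAVQAVGFDK
QKCAAENACVAWENIFVRILHYFLNYYRDLFQAMVCNMWDRFYNGLCVNYYMQYWKWGVF
GRCAKDDNMWWEGCVYQCYHVCGLNWFKGHCFMYERMYCCQMMKIGLACRAERQCVLLRA
AIVVRMGKDYAKNRKAAYINLYQQLDQGAIGKNACNDKEGQYQLDGYWTPGGCQHDKFFA
FADICYQENWKHHIWVRQLYIHQLCHINQYRNWKHHFFMQVN
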