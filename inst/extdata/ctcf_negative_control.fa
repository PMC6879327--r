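>ctcf_negative_control chr16:67594811-67594967
CCCCAAACTTATCTGGTCCCTTCACAGCAAAACCTCTCTCAAATTGCATACATGTGCTGT
CTCCATTTCCTCACTTTCCTGGTGACTGTTTAACCCATTCCGGTCAGGTCCACCTCCCTG
ATATACTCACGTGAATCAAGCCAAGGCCATCAGTGA
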