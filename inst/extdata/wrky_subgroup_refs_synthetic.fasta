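>IIa_ref1|IIa
KYSMIIRQDTYGQQYWRKYGQKPFIRSCPMMSCGFDRSTSTMEDDKFVFDSSVSYHLHNQ
YIDLEMLRIDIPQ
>IIa_ref2|IIa
KYSMIIRQDTYGQQYWRKYGQKQFDRSCPMMSCGFDRSTSTMEDDKTVFDSSVSYHAHNQ
YQDLEMIRFDIPQ
>IIa_ref3|IIa
KYSMIIRRDTAGQQYWRKDGVKQFDRSCPMMSCGFDRSTSTMEDDKFVFDSSVSYHFHNQ
YIDLEMLRFDIPQ
>IIb_ref1|IIb
NMDDQPYGMRAYSARWRKEGQKKSRDPCDPTMCYEINNMRGIILKEGSIPSFSFDHSHKP
AKQAPKPVLFILP
>IIb_ref2|IIb
NMDDQPYGMRAYGARWRKSGQKKSRMPCDPTMCYEIPNMRGIINKEGSIPSASFDHSHKP
AKQAPKPVLFSLP
>IIb_ref3|IIb
NMDDQPYGMMAYGARWRKYGQKKSRDPCDPTMCYEINNMRGIILKEGSIPSSFFDHSHKP
AKQAPKPVLQSLP
>IIc_ref1|IIc
PDFNFNISDPAVIKFWRKYGQKKALFACKNASCIVTTIFFGMQVFEFVLDPAMTYHYHVL
PPDQEFTPKEAYY
>IIc_ref2|IIc
PDFNFNISDPAVIKDWRKYGQNLALFACANAYCIVTTITFGMQVFEFVLDPAMTYHYHVL
PPDQEFTPKDAIY
>IIc_ref3|IIc
PDFNFNISDPAVIKDWRKYGQKLALFACAAASCIVTTIFFGMGVFEDVLDPAMTYHYHVL
PPDDEFTPKEAIY
>IId_ref1|IId
RNIAFEKMARQSSKEWRNYGQKSPMIACEPTTCPMLTIYRSFAIVENTTNENYEIHDHAD
KMFLPALQNKLIG
>IId_ref2|IId
RNIAFEKMARQSSKFWRKYGQTSPMIACERTTCPMLKIYRSFAIVENTTQEFYEIHDHAD
KPFLPALQNKLIG
>IId_ref3|IId
RNIAFEKMARQSSKFWRKYGQKSPMITCENFTCPMLKIYRSFAIVENTTNENYEIHDHAD
KMFLPLLQNKLIG
>IIe_ref1|IIe
PISLFELQKTFEGNGWRKYGQYNTARKCQDIVCTLFYVFGFEIYENNVKLEPADPHEHLM
MPAANVAVMLAYY
>IIe_ref2|IIe
PISLFELNKTFEGNGWRKYGQKNTARKCQDIVCTLFYVFYFEIYENMVDVEPADPHEHLM
MGAANVAFMLAYY
>IIe_ref3|IIe
PISLFELNKTFEGNGGRKYGQKNTAQKCQDIVCTLFAVFGFEIYENMVKVEQADPHEHLM
MPAANVAVMLAYY
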