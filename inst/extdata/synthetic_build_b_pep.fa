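>SYNP0005001.2 pep chromosome:SYN:1 gene:SYNG0000001.5 gene_biotype:protein_coding
WFEGQDHWYVVWAHVLKYWGEDWPRYWKDMVLHLGPFANFICSMPWSQQYSKKQGVSASI
NIDMSKSKLHLNALKFYYIFIVAILRH
>SYNP0005002.2 pep chromosome:SYN:1 gene:SYNG0000002.3 gene_biotype:protein_coding
QKHCWNEYNNVPGWLGREVVMDFNIFWGNFCQSFGRVLLDFEACQPNILENIAWQLSLYP
FCCITYNEILPCLDYYNKMWTPVPVVKHVMPAWD
>SYNP0005003.2 pep chromosome:SYN:1 gene:SYNG0000003.5 gene_biotype:protein_coding
MQLDITWPQMAWKNCKGVMDLESWGSGNDNLIPMDLRGRKAATDNQHLQHAWQCWHRDLP
ECIMAAGPYVGFYGGDPWTRHIA
>SYNP0005004.3 pep chromosome:SYN:1 gene:SYNG0000004.2 gene_biotype:protein_coding
ASKRKGKRCPFHGCISLIDIFHASPEDCDPNICYYGSYDYDYGNKCDCMEKIGSCHLEYP
R
>SYNP0005005.2 pep chromosome:SYN:1 gene:SYNG0000005.5 gene_biotype:protein_coding
YHHNKLKIYGPAHVRYYNHFCMCEPNNNAIILPHQSQNDGEVSYQLVEGTPGSSACHESF
TSESWCWIHRFFANNQMNHPVYPFCPFLTWVFPETYNQSLCGIWGFIEY
>SYNP0005006.2 pep chromosome:SYN:1 gene:SYNG0000006.2 gene_biotype:protein_coding
RFTGRSHRIKYKDRCWHTTHILIDPWKEWFYQSIPGECELEPPGKYYFYHVLTVQGDATN
YMKYDSVFANPPRFCMQCNWHCFPVWDYTIAAHGKERTKHNEDFMRHLWYSNMPT
>SYNP0005007.2 pep chromosome:SYN:1 gene:SYNG0000007.3 gene_biotype:protein_coding
MQLDITWPQMAWKNCKGVMDLESWGSGNDNLIPMDLRGRKAATDNQHLQHAWQCWHRDLP
ECIMAAGPYVGFYGGDPWTRHIA
>SYNP0005008.2 pep chromosome:SYN:1 gene:SYNG0000008.3 gene_biotype:protein_coding
ARKHITAKRQHQQVFEFWHPKDPYPCTFINFYINCHLMKAMTPWVKSISPDGRIKNVMTN
DPHDFSPETTYTWCASPSPFEFAHSPYVGVFNVNVGY
>SYNP0005009.2 pep chromosome:SYN:1 gene:SYNG0000009.3 gene_biotype:protein_coding
HTRTDHYYQPISMFITMVNIIFRLSSMALHNYLKESTPIFSSHFPIQEMITFFGVWDSIQ
LFTDWEP
>SYNP0005010.3 pep chromosome:SYN:1 gene:SYNG0000010.4 gene_biotype:protein_coding
RYMVCINMLRWWALYHTVWVQWHMVCPRGTLECGNEKRHALGSVLCQNSIFETEQWGAHP
YENRCGDWSIKVPKVHNSVEEPTYTMPKWPEVSPVPCYQPFIFNTKEPHALY
>SYNP0005011.2 pep chromosome:SYN:1 gene:SYNG0000011.3 gene_biotype:protein_coding
KPPLDTSTQYRKFQARHAMDEDTLRLEALRPFNVQYDCLKSVHKHMLWPHEYERVGDPAP
DDGFPYGGGEIKFKE
>SYNP0005012.1 pep chromosome:SYN:1 gene:SYNG0000013.2 gene_biotype:protein_coding
GFKFLTRDQVRQQAARNVRSQVENWHMYCLKETEVCFPAQS
>SYNP0005013.1 pep chromosome:SYN:1 gene:SYNG0000014.5 gene_biotype:protein_coding
HQEILDCFSSRDMNGQPAPYLFIPVIDRLGMGDWEEFWYNTSDTSETFCVMVDLYCTALL
WMTSKEGLMDCMRATWCWYIVSFIGTMKWKMMSKMLMI
>SYNP0005014.3 pep chromosome:SYN:1 gene:SYNG0000015.2 gene_biotype:protein_coding
IMDKENAQERQLWCNTLEATTMGYWHEQVHLGSHVATNEFSRRIHNMPPCYNTFYYWTID
SQWTTGIDGCEKPQR
>SYNP0005015.3 pep chromosome:SYN:1 gene:SYNG0000016.5 gene_biotype:protein_coding
RQPCIFIFTERHVWRTAEFNDVHWGKLMFSYGYFWRIARSFMREWCISDHHIHMQFNECT
LLMCAVGRLHPKSAKVDQHELLDTYPQNYTERDDYLYRGTADDTIKEKVRKSAFWTSDC
>SYNP0005016.2 pep chromosome:SYN:1 gene:SYNG0000017.2 gene_biotype:protein_coding
LTEIPDHNQQSFTQCINAMADHVTEECAYHKFNNKNMVDRWCSKPQCKNWNSPTLGPIKT
RAWPICPGLFNLDNPWEPNIETAWTTHNMQAFRVQCLSSAGGHRATNHERCCRSYWDASK
GPHYGS
>SYNP0005017.3 pep chromosome:SYN:1 gene:SYNG0000018.3 gene_biotype:protein_coding
TARMGIPETYSVSGCLAYRPQINHTNGIHMLRHSSYTLQVLYLDHRHSDSYAWWMPIGKI
FG
>SYNP0005018.3 pep chromosome:SYN:1 gene:SYNG0000019.3 gene_biotype:protein_coding
QFCNYIAGDIQMDAFPINMAIGRPTTLIFHTRQRKYHVYDENMVEIPLTENPVTFGHYVA
KWYANNTTEQMVLNLYEVWKHPCKQNVTPFFRELSHVIMFYVWDWHCPRHWPTSHA
>SYNP0005019.1 pep chromosome:SYN:1 gene:SYNG0000020.3 gene_biotype:protein_coding
SPAITQVKDCIIPYHHYNSADRCFYIIVRQEGYAHRKTIRERCPFPGVGRFKKNHQIWTH
AMSMIKALKAQPHCLHRYDFNVAWYHSPMARHNPAAMVVYHV
>SYNP0005020.1 pep chromosome:SYN:1 gene:SYNG0000021.2 gene_biotype:protein_coding
KSQCRYATMEDDKEHHRRTQGQIDTSINNLPEDQTSYRYYDKTHFEYTLTYTSDYTTVNK
CELRMALPNKFGYSVHICRTERNEYMGPSRESCIDKWVLRRLIDVMLLVDMHWHFYFTDN
HFRW
>SYNP0005021.1 pep chromosome:SYN:1 gene:SYNG0000022.5 gene_biotype:protein_coding
EDLMFWSECYKPYLSYQYTLGSALVDMMRAKFAVNYIMFSSTWPFHCQNFEVIWWACQLP
CNFVFMHTGNE
>SYNP0005022.1 pep chromosome:SYN:1 gene:SYNG0000023.5 gene_biotype:protein_coding
MYCDMWTKSLQYSWSHEEYWGWDDFEWCCQFSQDVQEGQNNGKVHYCLDNSHGLMGLTHM
HGYWGSNWMTPTCCMEEPENKQTNCEPLT
>SYNP0005023.1 pep chromosome:SYN:1 gene:SYNG0000024.2 gene_biotype:protein_coding
KCCHACGRWYHDRRIDRKKTLCDVTGHCNHLWSWNAMWKIGTWTFSCEVPAKCMHCELMH
STPSKLRGWDDHADWCCFIKNMITYCLEWDPWYMQDVPV
>SYNP0005024.2 pep chromosome:SYN:1 gene:GAIN0802_0000001.3 gene_biotype:protein_coding
RMSMRRYPRSNWAVIYINSCWWYIDAAYLSRMVVRHTFHHWVNDSMPRQHRMINYEWMDA
QAHKAACARRSNSTYVVVLGFAGARWWKL
>SYNP0005025.1 pep chromosome:SYN:1 gene:GAIN0802_0000002.5 gene_biotype:protein_coding
ASFMVMQLSIKKPFEGYWLCMWGFKFFGHAANWTKLDYQQMMCGQEAFCSLWSPQLIQGV
PYLVANR
>SYNP0005026.2 pep chromosome:SYN:1 gene:GAIN0802_0000003.4 gene_biotype:protein_coding
KVKVNKAGPVSWKDGPVSYHIDSFTHQWISFMSEAQGSGPRYFSFVYNWCWQDFKNGWSM
DKD
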