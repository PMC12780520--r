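country,region
Kyrgyz Republic,CA
Tajikistan,CA
Bolivia,LAC
Colombia,LAC
Dominican Republic,LAC
Guatemala,LAC
Guyana,LAC
Haiti,LAC
Honduras,LAC
Peru,LAC
Albania,NAWAE
Armenia,NAWAE
Azerbaijan,NAWAE
Egypt,NAWAE
Jordan,NAWAE
Turkey,NAWAE
Yemen,NAWAE
Papua New Guinea,Oceania
Bangladesh,SASEA
Cambodia,SASEA
India,SASEA
Maldives,SASEA
Myanmar,SASEA
Nepal,SASEA
Pakistan,SASEA
Timor-Leste,SASEA
Angola,SSA
Benin,SSA
Burkina Faso,SSA
Burundi,SSA
Cameroon,SSA
Chad,SSA
Comoros,SSA
Congo,SSA
Congo Democratic Republic,SSA
Cote d'Ivoire,SSA
Eswatini,SSA
Ethiopia,SSA
Gabon,SSA
Gambia,SSA
Ghana,SSA
Guinea,SSA
Kenya,SSA
Lesotho,SSA
Liberia,SSA
Madagascar,SSA
Malawi,SSA
Mali,SSA
Mauritania,SSA
Mozambique,SSA
Namibia,SSA
Niger,SSA
Nigeria,SSA
Rwanda,SSA
Sao Tome and Principe,SSA
Senegal,SSA
Sierra Leone,SSA
South Africa,SSA
Togo,SSA
Uganda,SSA
Zambia,SSA
Zimbabwe,SSA
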